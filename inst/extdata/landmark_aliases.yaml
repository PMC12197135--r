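# Landmark label aliases: free-text fiducial labels -> canonical codes.
# Canonical codes (R1..R7, P1..P7) always map to themselves.
aliases:
  BIF: P1
  L_REN: P2
  R_REN: P3
  L_HIL: P4
  R_HIL: P5
  SMA: P6
  CA: P7
  R_ASIS: R1
  L_ASIS: R2
  SYMPHYSIS: R3
  S1: R4
  L_RIB12: R5
  R_RIB12: R6
  STERNUM: R7
# Landmarks excluded from analysis by default (overridable per run).
excluded:
  - R7
# Label prefixes excluded from analysis by default (skin fiducials).
prefix_excluded:
  - SKIN_
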