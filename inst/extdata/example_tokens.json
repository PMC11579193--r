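{
  "ADVAN": [
    ["$SUBROUTINE ADVAN1", ";; one compartment\n  V=V1\n  S1=V1"],
    ["$SUBROUTINE ADVAN3", ";; two compartments\n  V=V1\n  S1=V1\n  Q=THETA(QIDX)\n  V2=THETA(V2IDX)"],
    ["$SUBROUTINE ADVAN11", ";; three compartments\n  V=V1\n  S1=V1\n  Q2=THETA(Q2IDX)\n  V2=THETA(V2IDX)\n  Q3=THETA(Q3IDX)\n  V3=THETA(V3IDX)"]
  ],
  "BSVQ2": [[""], ["*EXP(ETA(BSVQ2IDX))"]],
  "BSVQ3": [[""], ["*EXP(ETA(BSVQ3IDX))"]],
  "BSVV2": [[""], ["*EXP(ETA(BSVV2IDX))"]],
  "BSVV3": [[""], ["*EXP(ETA(BSVV3IDX))"]],
  "Q_WT":  [[""], ["*(WT/70)**THETA(QWTIDX)"]],
  "Q2_WT": [[""], ["*(WT/70)**THETA(Q2WTIDX)"]],
  "V_WT":  [[""], ["*(WT/70)**THETA(VWTIDX)"]],
  "V2_WT": [[""], ["*(WT/70)**THETA(V2WTIDX)"]],
  "V3_WT": [[""], ["*(WT/70)**THETA(V3WTIDX)"]],
  "V_AGE": [[""], ["*(AGE/40)**THETA(VAGEIDX)"]],
  "V_SEX": [[""], ["*EXP(THETA(VSEXIDX)*SEX)"]],
  "CL_SEX": [[""], ["*EXP(THETA(CLSEXIDX)*SEX)"]],
  "CL_WT": [[""], ["*(WT/70)**THETA(CLWTIDX)"]],
  "CL_SCR": [[""], ["*(SCR/1.0)**THETA(CLSCRIDX)"]],
  "CL_AGE": [[""], ["*(AGE/40)**THETA(CLAGEIDX)"]],
  "IOVCL": [[""], ["*EXP(IOV1*OCC1+IOV2*OCC2)"]],
  "IOVQ2": [[""], ["*EXP(IOV3*OCC1+IOV4*OCC2)"]],
  "IOVV":  [[""], ["*EXP(IOV5*OCC1+IOV6*OCC2)"]],
  "RESERR": [
    ["W=SQRT(THETA(PERRIDX)**2*IPRED**2+THETA(AERRIDX)**2)"],
    ["W=THETA(PERRIDX)*IPRED"]
  ]
}
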