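$PROBLEM intravenous population PK structure candidate
$INPUT ID TIME AMT DV WT AGE SEX SCR OCC1 OCC2
$DATA data.csv IGNORE=@
{ADVAN[0]}
$PK
{ADVAN[1]}
  CL=THETA(1){CL_WT[0]}{CL_AGE[0]}{CL_SCR[0]}{CL_SEX[0]}*EXP(ETA(1)){IOVCL[0]}
  V1=THETA(2){V_WT[0]}{V_AGE[0]}{V_SEX[0]}*EXP(ETA(2)){IOVV[0]}
  QSCALE=1{Q_WT[0]}{Q2_WT[0]}{BSVQ2[0]}{BSVQ3[0]}{IOVQ2[0]}
  VSCALE=1{V2_WT[0]}{V3_WT[0]}{BSVV2[0]}{BSVV3[0]}
$ERROR
  IPRED=F
  {RESERR[0]}
  Y=IPRED+W*EPS(1)
$ESTIMATION METHOD=1 INTERACTION MAXEVAL=9999 PRINT=5
$COVARIANCE UNCONDITIONAL
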