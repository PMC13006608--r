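variable,B,SE,ExpB,ci_lower,ci_upper
ODS,0.142,0.036,1.153,1.073,1.238
AIS_weighted,1.907,0.545,6.736,2.313,19.612
HR,0.045,0.012,1.046,1.023,1.070
ALB,-0.092,0.032,0.912,0.857,0.970
ADA,-0.207,0.067,0.813,0.713,0.926
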