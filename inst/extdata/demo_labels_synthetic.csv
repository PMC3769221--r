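"sample","status","stratum"
"S0001","case","fetal"
"S0002","case","fetal"
"S0003","control","fetal"
"S0004","control","fetal"
"S0005","control","fetal"
"S0006","case","fetal"
"S0007","control","fetal"
"S0008","control","fetal"
"S0009","case","fetal"
"S0010","control","fetal"
"S0011","case","fetal"
"S0012","case","fetal"
"S0013","case","fetal"
"S0014","case","fetal"
"S0015","control","fetal"
"S0016","control","fetal"
"S0017","case","fetal"
"S0018","case","fetal"
"S0019","case","fetal"
"S0020","control","fetal"
"S0021","case","fetal"
"S0022","case","fetal"
"S0023","control","fetal"
"S0024","case","fetal"
"S0025","case","fetal"
"S0026","control","fetal"
"S0027","control","fetal"
"S0028","control","fetal"
"S0029","control","fetal"
"S0030","control","fetal"
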