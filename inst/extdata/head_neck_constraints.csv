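structure,constraint,importance,scoreWeight,exclude,excludeMarginMM
ctv_high,V66.5Gy > 95%,hard,1,,0
ctv_high,V74.9Gy < 1 cc,hard,1,,0
ctv_low,V51.3Gy > 95%,hard,1,,0
ctv_low,V57.8Gy < 1 cc,soft,1,ctv_high,10
brainstem,max < 54Gy,hard,1,,0
spinal_cord,max < 45Gy,hard,1,,0
constrictors,mean < 42Gy,hard,1,,0
larynx,mean < 40Gy,hard,1,,0
parotids,mean < 26Gy,hard,1,,0
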