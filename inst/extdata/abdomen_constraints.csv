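structure,constraint,importance,scoreWeight,exclude,excludeMarginMM
ctv,V47.5Gy > 95%,soft,1,,0
stomach,V33Gy < 1 cc,hard,1,,0
small_bowel,V33Gy < 1 cc,hard,1,,0
large_bowel,V33Gy < 1 cc,hard,1,,0
duodenum,V33Gy < 1 cc,hard,1,,0
spinal_cord,V25Gy < 0.5 cc,hard,1,,0
kidneys,mean < 10Gy,hard,1,,0
liver,mean < 20Gy,hard,1,,0
liver,Vtot-V15Gy > 700 cc,hard,1,,0
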