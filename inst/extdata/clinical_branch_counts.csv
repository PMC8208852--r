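dataset,n_layers,left_total,left_misjudged,right_total,right_misjudged,left_acc_printed,right_acc_printed,runtime_s
1,368,943,123,532,59,86.76,85.74,46
2,386,498,68,506,70,86.34,86.03,49
3,378,624,84,587,85,85.74,85.12,52
4,403,486,79,619,95,83.79,84.64,48
5,436,536,89,472,74,83.40,84.32,52
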