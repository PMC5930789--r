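algorithm_number,window,tier,source_rule,se,se_lo,se_hi,sp,sp_lo,sp_hi,ppv,ppv_lo,ppv_hi,npv,npv_lo,npv_hi,a,a_lo,a_hi
1,PRE90_POST90,CONSERVATIVE,H1,50,47.2,52.8,92.5,90.9,94.0,88.8,86.4,91.0,60.9,58.5,63.3,69.4,67.6,71.3
2,PRE90_POST90,CONSERVATIVE,H1_OR_O2,57.8,55.1,60.5,86.9,84.8,88.8,84,81.4,86.3,63.4,60.9,65.9,71,69.2,72.9
3,PRE90_POST90,CONSERVATIVE,H1_OR_O1,61.2,58.5,63.9,84.2,82.0,86.3,82.1,79.6,84.6,64.6,62.1,67.1,71.7,69.8,73.5
4,PRE90_POST90,LESS_CONSERVATIVE,H1,52.9,50.2,55.7,87.9,85.9,89.8,83.8,81.2,86.3,61.1,58.6,63.5,68.9,67.0,70.8
5,PRE90_POST90,LESS_CONSERVATIVE,H1_OR_O2,60.4,57.7,63.2,82.2,79.9,84.4,80.1,77.6,82.6,63.6,61.0,66.1,70.3,68.5,72.1
6,PRE90_POST90,LESS_CONSERVATIVE,H1_OR_O1,64.2,61.5,66.8,79.7,77.4,82.2,79,76.5,81.4,65.2,62.5,67.8,71.3,69.5,73.1
7,PRE90_POST90,INCLUSIVE,H1,53.6,50.9,56.4,86.9,84.8,88.9,82.9,80.3,85.5,61.2,58.7,63.7,68.8,66.9,70.7
8,PRE90_POST90,INCLUSIVE,H1_OR_O2,69.5,66.9,72.0,68,65.2,70.8,72.1,69.4,74.5,65.2,62.4,68.0,68.8,66.9,70.6
9,PRE90_POST90,INCLUSIVE,H1_OR_O1,76.3,73.9,78.6,58.7,55.8,61.7,68.7,66.2,71.1,67.5,64.4,70.5,68.2,66.3,70.1
10,PRE180_POST180,CONSERVATIVE,H1,57.5,54.7,60.3,90.1,88.3,91.8,87.4,85.0,89.5,64.1,61.7,66.6,72.4,70.6,74.2
11,PRE180_POST180,CONSERVATIVE,H1_OR_O2,65.8,63.2,68.4,82.3,80.0,84.6,81.6,79.2,83.9,66.9,64.4,69.5,73.3,71.6,75.1
12,PRE180_POST180,CONSERVATIVE,H1_OR_O1,68.6,66.1,71.2,79.1,76.7,81.6,79.6,77.2,82.0,67.9,65.3,70.5,73.4,71.6,75.1
13,PRE180_POST180,LESS_CONSERVATIVE,H1,60.1,57.4,NA,84.4,82.2,86.5,82.1,79.6,84.5,64,61.5,66.5,71.2,69.4,73.0
14,PRE180_POST180,LESS_CONSERVATIVE,H1_OR_O2,68.1,65.6,70.6,77.1,74.5,79.6,77.9,75.4,80.3,67,64.4,69.7,72.2,70.4,74.0
15,PRE180_POST180,LESS_CONSERVATIVE,H1_OR_O1,71,68.6,73.5,73.8,71.2,76.4,76.3,73.9,78.7,68.2,65.5,70.9,72.3,70.5,74.0
16,PRE180_POST180,INCLUSIVE,H1,61.1,58.4,63.8,83,80.7,85.2,81,78.5,83.4,64.2,61.7,66.8,71.1,69.3,73.0
17,PRE180_POST180,INCLUSIVE,H1_OR_O2,77.4,75.1,79.7,57.8,54.8,60.6,68.5,66.0,70.9,68.2,65.3,71.3,68.4,66.6,70.2
18,PRE180_POST180,INCLUSIVE,H1_OR_O1,82.7,80.6,84.8,48.2,45.2,51.2,65.5,63.1,67.8,70.1,66.7,73.5,66.9,65.0,68.9
19,PRE90_NOLIMIT,CONSERVATIVE,H1,70.7,68.1,73.2,69.9,67.1,72.6,73.6,71.0,76.0,66.7,63.9,69.5,70.3,68.4,72.1
20,PRE90_NOLIMIT,CONSERVATIVE,H1_OR_O2,77.4,75.1,79.6,60.4,57.5,63.3,69.9,67.5,72.3,69.2,66.2,72.2,69.6,67.8,71.5
21,PRE90_NOLIMIT,CONSERVATIVE,H1_OR_O1,80.2,78.0,82.4,55.6,52.7,58.6,68.2,65.8,70.6,70.2,67.1,73.3,68.9,67.1,70.9
22,PRE90_NOLIMIT,LESS_CONSERVATIVE,H1,72.9,70.5,75.3,63.9,61.1,66.8,70.6,68.1,72.9,66.6,63.6,69.4,68.8,66.9,70.6
23,PRE90_NOLIMIT,LESS_CONSERVATIVE,H1_OR_O2,79.3,77.1,81.5,55,52.1,58.0,67.7,65.3,70.0,69.1,66.0,72.2,68.3,66.4,70.1
24,PRE90_NOLIMIT,LESS_CONSERVATIVE,H1_OR_O1,82.2,80.1,84.3,50.4,47.5,53.4,66.3,64.0,68.6,70.4,67.2,73.7,67.7,65.8,69.6
25,PRE90_NOLIMIT,INCLUSIVE,H1,74,71.6,76.4,62,59.2,64.9,69.8,67.4,72.2,66.8,63.9,69.7,68.6,66.6,70.4
26,PRE90_NOLIMIT,INCLUSIVE,H1_OR_O2,86.5,84.7,88.4,35.3,32.5,38.2,61.4,59.1,63.6,68.8,65.1,72.6,63.2,61.2,65.1
27,PRE90_NOLIMIT,INCLUSIVE,H1_OR_O1,90.1,88.4,91.7,27.6,24.9,30.2,59.7,57.4,61.8,70,65.7,74.4,61.5,59.6,63.5
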