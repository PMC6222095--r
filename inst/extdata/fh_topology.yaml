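domains:
- first: 1.0
  last: 61.0
- first: 66.0
  last: 126.0
- first: 131.0
  last: 191.0
- first: 196.0
  last: 256.0
- first: 263.0
  last: 323.0
- first: 330.0
  last: 390.0
- first: 395.0
  last: 455.0
- first: 460.0
  last: 520.0
- first: 527.0
  last: 587.0
- first: 594.0
  last: 654.0
- first: 659.0
  last: 719.0
- first: 724.0
  last: 784.0
- first: 789.0
  last: 849.0
- first: 856.0
  last: 916.0
- first: 923.0
  last: 983.0
- first: 988.0
  last: 1048.0
- first: 1055.0
  last: 1115.0
- first: 1122.0
  last: 1182.0
- first: 1187.0
  last: 1247.0
- first: 1252.0
  last: 1312.0
linkers:
- first: 62
  last: 65
  movable: no
- first: 127
  last: 130
  movable: no
- first: 192
  last: 195
  movable: no
- first: 257
  last: 262
  movable: yes
- first: 324
  last: 329
  movable: yes
- first: 391
  last: 394
  movable: no
- first: 456
  last: 459
  movable: no
- first: 521
  last: 526
  movable: yes
- first: 588
  last: 593
  movable: yes
- first: 655
  last: 658
  movable: no
- first: 720
  last: 723
  movable: no
- first: 785
  last: 788
  movable: no
- first: 850
  last: 855
  movable: yes
- first: 917
  last: 922
  movable: yes
- first: 984
  last: 987
  movable: no
- first: 1049
  last: 1054
  movable: yes
- first: 1116
  last: 1121
  movable: yes
- first: 1183
  last: 1186
  movable: no
- first: 1248
  last: 1251
  movable: no
glycan_sites:
- 557
- 754
- 819
- 886
- 953
- 968
- 1085
- 1217
reference_domains:
  first: 594
  last: 849
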