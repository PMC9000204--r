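"sample_id","lab1","lab2","lab3","lab4","lab5","lab6"
"A",1074.4,981.4,927.1,1008.6,1049,1027.7
"B",574.9,497.3,492.5,513.2,501.5,532.1
"C",384.1,326.4,282.4,347.8,314.4,349.7
"D",322.4,266.4,244.5,293.8,248.5,239.7
"E",219.6,183.3,163.4,209.6,174.4,202.3
"F",186.5,155.9,148.3,175.7,143,169.4
"G",121.9,105.2,88.8,115,95.6,112.7
"H",88.9,74.55,64.2,82.7,68.7,82.9
"I",68,56.55,51.7,65.4,53.2,60.5
"J",30.3,25.8,26.4,26.4,28.1,26.8
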