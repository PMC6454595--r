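卵巢切除术	手术	3
左附件区	解剖部位	4
疼痛不适	症状描述	2
胃	解剖部位	6
腹部	解剖部位	5
贝伐珠单抗	药物	2
附件区	解剖部位	2
饮食睡眠不佳	独立症状	2
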