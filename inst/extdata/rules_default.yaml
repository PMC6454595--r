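- kind: strip_suffix
  category:
  - anatomy
  tokens:
  - 旁
- kind: prefix_merge
  category:
  - anatomy
  tokens:
  - 右上
  - 左上
  - 右
  - 左
- kind: suffix_merge
  category:
  - anatomy
  tokens:
  - 周
  - 上
  - 下
  - 外
- kind: suffix_merge
  category:
  - surgery
  tokens:
  - 手术
  - 术
- kind: gazetteer_extract
  category:
  - anatomy
  - surgery
  tokens: []
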