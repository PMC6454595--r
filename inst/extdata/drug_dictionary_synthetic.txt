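# Synthetic fixture drug dictionary (product names, trade names, abbreviations).
# One name per line; # lines are comments.
贝伐珠单抗
奥沙利铂
卡培他滨
紫杉醇
顺铂
氟尿嘧啶
吉西他滨
依托泊苷
多西他赛
环磷酰胺
表柔比星
CPT-11
CPT
5-FU
5FU
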