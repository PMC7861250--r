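# Sentence templates for the synthetic report generator: slot<TAB>template
# Placeholders: {site} {organ} {specific} {mal} {density} {size} {phrase}
# Users may add templates per slot; the generator samples uniformly within a slot.
primary_direct	{site}见软组织肿块影,考虑{mal}。
primary_direct	{site}占位性病变,{mal}可能性大。
primary_direct	{site}病变,符合{mal}表现。
primary_approx	{organ}{mal}术后改变。
primary_approx	{organ}{mal}治疗后复查。
primary_specific	{specific}见不规则肿块影。
primary_specific	{specific}见团片状密度增高影。
size	{site}示{density},大小约{size},边缘模糊。
size	{site}见{density},范围约{size}。
size	{site}结节影,大小约{size},可见强化。
meta_sentence	{phrase},考虑转移。
meta_sentence	{phrase},考虑多发转移。
meta_sentence	{phrase},转移可能。
meta_negation	{phrase},转移不除外。
filler	对比前片无著变。
filler	请结合临床及其他检查。
filler	建议随诊复查。
filler	增强扫描未见明显异常强化。
filler	余所见大致同前。
filler	扫描野内未见其他明显异常。
filler	双侧胸廓对称。
filler	气管居中,未见狭窄。
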