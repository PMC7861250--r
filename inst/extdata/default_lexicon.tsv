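# Default lexicon: term<TAB>category
# categories: anatomy | malignancy | density | metastasis | descriptor | conjunction
# Anatomy seed dictionary (~150 terms). Coverage is a data concern:
# replace this file wholesale to adapt the extractor to other tumor domains.
肺	anatomy
左肺	anatomy
右肺	anatomy
双肺	anatomy
左肺上叶	anatomy
左肺下叶	anatomy
左肺舌叶	anatomy
右肺上叶	anatomy
右肺中叶	anatomy
右肺下叶	anatomy
肺尖	anatomy
肺门	anatomy
左肺门	anatomy
右肺门	anatomy
左侧肺门	anatomy
右侧肺门	anatomy
支气管	anatomy
主支气管	anatomy
气管	anatomy
气管隆突	anatomy
胸膜	anatomy
左侧胸膜	anatomy
右侧胸膜	anatomy
胸壁	anatomy
胸腔	anatomy
纵隔	anatomy
前纵隔	anatomy
后纵隔	anatomy
上纵隔	anatomy
中纵隔	anatomy
心包	anatomy
心脏	anatomy
乳	anatomy
乳腺	anatomy
左乳	anatomy
右乳	anatomy
左侧乳腺	anatomy
右侧乳腺	anatomy
乳头	anatomy
乳晕	anatomy
腋窝	anatomy
左腋窝	anatomy
右腋窝	anatomy
淋巴结	anatomy
锁骨上	anatomy
锁骨下	anatomy
颈部	anatomy
颈根部	anatomy
肝	anatomy
肝脏	anatomy
肝左叶	anatomy
肝右叶	anatomy
肝门	anatomy
胆囊	anatomy
胆管	anatomy
脾	anatomy
脾脏	anatomy
脾门	anatomy
胰腺	anatomy
胰头	anatomy
胰体	anatomy
肾	anatomy
左肾	anatomy
右肾	anatomy
肾上腺	anatomy
左侧肾上腺	anatomy
右侧肾上腺	anatomy
双侧肾上腺	anatomy
肾门	anatomy
输尿管	anatomy
膀胱	anatomy
前列腺	anatomy
精囊腺	anatomy
子宫	anatomy
宫颈	anatomy
卵巢	anatomy
附件区	anatomy
阴道	anatomy
胃	anatomy
胃窦	anatomy
胃底	anatomy
贲门	anatomy
幽门	anatomy
食管	anatomy
十二指肠	anatomy
空肠	anatomy
回肠	anatomy
结肠	anatomy
升结肠	anatomy
横结肠	anatomy
降结肠	anatomy
乙状结肠	anatomy
直肠	anatomy
阑尾	anatomy
腹膜	anatomy
腹膜后	anatomy
大网膜	anatomy
肠系膜	anatomy
腹腔	anatomy
盆腔	anatomy
腹壁	anatomy
腹股沟	anatomy
膈	anatomy
膈肌	anatomy
甲状腺	anatomy
左侧甲状腺	anatomy
右侧甲状腺	anatomy
甲状腺左叶	anatomy
甲状腺右叶	anatomy
腮腺	anatomy
颌下腺	anatomy
鼻咽	anatomy
口咽	anatomy
喉	anatomy
舌	anatomy
扁桃体	anatomy
脑	anatomy
颅内	anatomy
脑实质	anatomy
小脑	anatomy
脑膜	anatomy
垂体	anatomy
眼眶	anatomy
骨	anatomy
骨骼	anatomy
颅骨	anatomy
椎体	anatomy
颈椎	anatomy
胸椎	anatomy
腰椎	anatomy
骶骨	anatomy
骨盆	anatomy
髂骨	anatomy
耻骨	anatomy
股骨	anatomy
肱骨	anatomy
肋骨	anatomy
胸骨	anatomy
肩胛骨	anatomy
锁骨	anatomy
胸腺	anatomy
皮下	anatomy
皮肤	anatomy
肌肉	anatomy
软组织	anatomy
血管	anatomy
主动脉	anatomy
下腔静脉	anatomy
门静脉	anatomy
脐部	anatomy
# Malignancy indicators (primary-site sentence filter)
癌	malignancy
恶性	malignancy
瘤	malignancy
MT	malignancy
CA	malignancy
# Density indicators (rank size-bearing sentences)
高密度影	density
低密度影	density
不规则团块	density
软组织密度灶	density
占位	density
# Metastasis keywords (key-sentence acquisition)
转移	metastasis
考虑转移	metastasis
多发转移	metastasis
# Descriptor terms stripped from anatomic phrases
多发肿大	descriptor
多发	descriptor
肿大	descriptor
散在	descriptor
数枚	descriptor
可疑	descriptor
增大	descriptor
稍大	descriptor
小	descriptor
# Conjunction tokens (coordination-ellipsis completion splits on these)
、	conjunction
及	conjunction
与	conjunction
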