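sex,age,category,n
men,55,no_neoplasm,110521
men,55,nonadvanced_adenoma,23315
men,55,advanced_adenoma,8490
men,55,cancer,656
men,60,no_neoplasm,67635
men,60,nonadvanced_adenoma,17037
men,60,advanced_adenoma,7323
men,60,cancer,792
women,55,no_neoplasm,174774
women,55,nonadvanced_adenoma,19894
women,55,advanced_adenoma,6501
women,55,cancer,507
women,60,no_neoplasm,95930
women,60,nonadvanced_adenoma,13006
women,60,advanced_adenoma,5010
women,60,cancer,511
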