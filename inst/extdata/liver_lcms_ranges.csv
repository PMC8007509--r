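sample_id,low,high,flag
dog_liver_1,150,220,ok
dog_liver_2,120,250,ok
dog_liver_3,NA,NA,>ULOQ
dog_liver_4,1550,1650,ok
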