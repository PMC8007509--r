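sample_id,dose_mg_kg,dosed_compound,compound,region,conc,sd,n,flag
dog_liver_1,65,cmpdB,cmpdA,lesion,526,156,3,ok
dog_liver_1,65,cmpdB,cmpdA,connective,79,27,3,ok
dog_liver_1,65,cmpdB,cmpdA,parenchyma,242,59,3,ok
dog_liver_1,65,cmpdB,cmpdB,lesion,316,115,3,ok
dog_liver_1,65,cmpdB,cmpdB,connective,172,71,3,ok
dog_liver_1,65,cmpdB,cmpdB,parenchyma,495,78,3,ok
dog_liver_2,65,cmpdB,cmpdA,lesion,588,126,3,ok
dog_liver_2,65,cmpdB,cmpdA,connective,136,98,3,ok
dog_liver_2,65,cmpdB,cmpdA,parenchyma,577,227,3,ok
dog_liver_2,65,cmpdB,cmpdB,lesion,100,21,3,ok
dog_liver_2,65,cmpdB,cmpdB,connective,58,84,3,ok
dog_liver_2,65,cmpdB,cmpdB,parenchyma,269,103,3,ok
dog_liver_3,65,cmpdA,cmpdA,lesion,2549,673,3,ok
dog_liver_3,65,cmpdA,cmpdA,connective,2302,966,3,ok
dog_liver_3,65,cmpdA,cmpdA,parenchyma,NA,NA,3,>ULOQ
dog_liver_3,65,cmpdA,cmpdB,lesion,NA,NA,3,ND
dog_liver_3,65,cmpdA,cmpdB,connective,NA,NA,3,ND
dog_liver_3,65,cmpdA,cmpdB,parenchyma,NA,NA,3,ND
dog_liver_4,15,cmpdA,cmpdA,lesion,465,NA,1,ok
dog_liver_4,15,cmpdA,cmpdA,connective,366,28,2,ok
dog_liver_4,15,cmpdA,cmpdA,parenchyma,480,50,3,ok
dog_liver_4,15,cmpdA,cmpdB,lesion,NA,NA,3,ND
dog_liver_4,15,cmpdA,cmpdB,connective,NA,NA,3,ND
dog_liver_4,15,cmpdA,cmpdB,parenchyma,NA,NA,3,ND
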