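name,file,description,units,md5
table1,table1_biochar_fbioa.csv,Bioaccessibility of phenanthrene and pyrene on 12 biochar fine-particle matrices in Gamble's solution and ALF at 10 ug/g loading; printed DI under the extreme biochar scenario is an expected-output column,fbioa_percent: percent; q_ug_g: ug/g; di: ng/kg/day,5a40a97bf48c3fb56a6ac296c5e18bf3
table2,table2_loading_fbioa.csv,Bioaccessibility in Gamble's solution at 10/50/100 ug/g loadings on W500/C500/S500; printed DI under the extreme biochar scenario is an expected-output column,fbioa_percent: percent; q_ug_g: ug/g; di: ng/kg/day,6cc8ee2872581832766c2587c03f6914
pm25,pm25_pahs.csv,Urban PM2.5 PAH profile (Nanjing): TEF; mean concentration; SELF bioaccessibility at canonical precision (fbioa_percent) and 3-significant-figure display precision (fbioa_display_percent); printed ADI/DI/AC/BC and risk flags are expected-output columns; Nap has no bioaccessibility measurement,tef: dimensionless; c: ng/m3; fbioa: percent; di/adi: ng/kg/day; ac/bc: ng/m3,b492985efaa12ed6b6121d371bf6538d
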