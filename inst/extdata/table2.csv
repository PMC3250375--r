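study_id,year,ethnicity,phenotype,n_gg,n_gt,n_tt
study_2008a,2008,Japanese,pcv,15,49,45
study_2008a,2008,Japanese,control,39,32,14
study_2008b,2008,Chinese,pcv,17,30,25
study_2008b,2008,Chinese,control,33,48,12
study_2009,2009,Japanese,neovascular_amd,18,30,52
study_2009,2009,Japanese,pcv,18,50,32
study_2009,2009,Japanese,control,85,84,20
study_2010,2010,Japanese,neovascular_amd,67,155,183
study_2010,2010,Japanese,pcv,122,216,171
study_2010,2010,Japanese,control,502,638,196
study_2011,2011,Japanese,neovascular_amd,6,20,24
study_2011,2011,Japanese,pcv,22,20,18
study_2011,2011,Japanese,control,64,58,16
this_study,2011,Japanese,neovascular_amd,26,81,74
this_study,2011,Japanese,pcv,42,77,79
this_study,2011,Japanese,control,79,94,30
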