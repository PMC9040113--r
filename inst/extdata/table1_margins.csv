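site,age_group,individuals,female,female_pct,fu_median,fu_q1,fu_q3,cvd_deaths,primary_cancer_deaths,all_cancer_deaths
bladder,40-59,1288,324,25.2,7.7,3.9,11.9,32,99,172
bladder,60-79,5640,1230,21.8,5.3,2.4,9.1,598,714,1316
bladder,80+,2080,594,28.6,3.1,1.3,5.7,367,384,600
breast,40-59,12208,12208,100.0,7.1,3.6,11.4,88,1486,1713
breast,60-79,12669,12669,100.0,6.1,3.0,9.9,661,1701,2304
breast,80+,3793,3793,100.0,3.2,1.4,5.9,646,879,1064
colorectal,40-59,3029,1364,45.0,5.4,2.0,10.1,29,690,856
colorectal,60-79,10029,4125,41.1,4.6,1.9,8.5,638,2189,3057
colorectal,80+,3471,1881,54.2,2.9,1.0,5.8,500,948,1304
leukemia,40-59,903,344,38.1,5.8,2.7,9.6,16,168,198
leukemia,60-79,2217,885,39.9,4.7,2.0,8.0,151,489,664
leukemia,80+,759,371,48.9,2.6,1.0,5.3,114,177,234
lung,40-59,1044,510,48.9,1.5,0.5,5.2,25,593,631
lung,60-79,4102,1723,42.0,1.3,0.5,3.9,183,2373,2544
lung,80+,1016,504,49.6,0.9,0.4,2.2,93,607,646
melanoma,40-59,2850,1673,58.7,6.9,3.4,10.8,12,200,256
melanoma,60-79,3396,1684,49.6,5.4,2.5,9.2,197,358,556
melanoma,80+,1030,599,58.2,3.1,1.3,5.9,158,122,229
nhl,40-59,1450,622,42.9,6.4,3.0,10.6,25,200,263
nhl,60-79,2674,1293,48.4,4.8,2.1,8.1,203,535,718
nhl,80+,721,418,58.0,2.9,1.3,5.1,114,188,250
prostate,40-59,2341,0,0.0,5.8,2.9,9.4,29,229,264
prostate,60-79,16742,0,0.0,5.1,2.5,8.5,1182,2647,3533
prostate,80+,4677,0,0.0,2.9,1.3,5.1,818,1271,1560
uterus,40-59,1133,1133,100.0,7.2,3.6,11.2,18,88,128
uterus,60-79,2328,2328,100.0,5.5,2.4,9.2,120,325,473
uterus,80+,438,438,100.0,3.5,1.2,6.0,74,98,133
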