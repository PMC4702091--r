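parameter,group,mean,sd
n,HC,31,NA
n,tSCI,14,NA
n,pSCI,14,NA
n_male,HC,23,NA
n_male,tSCI,14,NA
n_male,pSCI,12,NA
n_female,HC,8,NA
n_female,tSCI,0,NA
n_female,pSCI,2,NA
age,HC,42.1,9.9
age,tSCI,47.6,14.5
age,pSCI,45.2,10.3
duration,HC,NA,NA
duration,tSCI,10.5,7.2
duration,pSCI,14.5,8.9
sca,HC,79.2,9.1
sca,tSCI,56.0,10.2
sca,pSCI,65.1,5.1
apw,HC,8.7,1.2
apw,tSCI,5.4,0.9
apw,pSCI,6.2,1.5
lrw,HC,9.8,1.0
lrw,tSCI,9.4,1.0
lrw,pSCI,10.2,0.7
von_frey,HC,14.9,2.09
von_frey,tSCI,5.2,3.1
von_frey,pSCI,15.2,3.1
warm_perception_threshold,HC,38.7,1.0
warm_perception_threshold,tSCI,41.6,2.6
warm_perception_threshold,pSCI,39.3,2.5
pain_threshold,HC,51.4,1.7
pain_threshold,tSCI,54.8,0.2
pain_threshold,pSCI,49.2,3.3
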