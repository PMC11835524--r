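measure,statistic,year,count
total,incidence,2000,330413
total,incidence,2019,368892
total,incidence,2020,448894
total,incidence,2021,494036
orphanhood,incidence,2000,262036
orphanhood,incidence,2019,292118
orphanhood,incidence,2020,360192
orphanhood,incidence,2021,407377
primary_grandparent,incidence,2000,31574
primary_grandparent,incidence,2019,29976
primary_grandparent,incidence,2020,34014
primary_grandparent,incidence,2021,32738
secondary_grandparent,incidence,2000,40106
secondary_grandparent,incidence,2019,50404
secondary_grandparent,incidence,2020,58938
secondary_grandparent,incidence,2021,57914
total,prevalence,2000,2700285
total,prevalence,2019,2663581
total,prevalence,2020,2772616
total,prevalence,2021,2912817
orphanhood,prevalence,2000,2220606
orphanhood,prevalence,2019,2159537
orphanhood,prevalence,2020,2251322
orphanhood,prevalence,2021,2378250
primary_grandparent,prevalence,2000,221982
primary_grandparent,prevalence,2019,212330
primary_grandparent,prevalence,2020,215695
primary_grandparent,prevalence,2021,217560
secondary_grandparent,prevalence,2000,281227
secondary_grandparent,prevalence,2019,315613
secondary_grandparent,prevalence,2020,330258
secondary_grandparent,prevalence,2021,342214
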