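table,capital,modifier,age_stratum,ref_with,ref_without,s10_with,s10_without,s01_with,s01_without,s11_with,s11_without,pr10,pr01,pr11,pr_stress_high_capital,pr_stress_low_capital,printed_reri,printed_ap_pct
2,social,low_belonging,30-44,1442,2794,623,784,793,1000,462,407,1.31,1.30,1.57,1.31,1.20,-0.04,NA
2,social,living_alone,30-44,1628,2791,769,878,444,765,237,228,1.28,0.97,1.33,1.28,1.38,0.08,6.0
2,social,low_belonging,45-59,1335,2997,448,664,630,987,421,339,1.31,1.26,1.79,1.31,1.42,0.22,12.3
2,social,living_alone,45-59,1215,2583,492,636,665,1268,346,338,1.37,1.05,1.54,1.37,1.47,0.12,7.8
2,social,low_belonging,60-74,818,2587,149,226,297,583,107,78,1.65,1.40,2.36,1.64,1.69,0.71,30.1
2,social,living_alone,60-74,649,2043,135,190,424,1072,115,97,1.71,1.14,2.10,1.69,1.85,0.25,12.5
3,economic,low_income,30-44,1753,3298,781,993,500,533,316,202,1.28,1.31,1.65,1.28,1.25,0.06,3.6
3,economic,no_insurance,30-44,1656,2982,795,934,589,848,299,261,1.29,1.10,1.45,1.29,1.31,0.06,4.1
3,economic,renter,30-44,1501,2885,667,892,727,894,411,287,1.25,1.30,1.74,1.26,1.31,0.19,10.9
3,economic,low_income,45-59,1488,3315,586,828,505,714,293,185,1.34,1.31,1.94,1.34,1.49,0.29,14.9
3,economic,no_insurance,45-59,1331,2898,625,749,665,1129,248,260,1.45,1.16,1.50,1.45,1.30,-0.11,NA
3,economic,renter,45-59,1514,3409,580,818,462,580,288,185,1.35,1.43,1.98,1.36,1.34,0.20,10.1
3,economic,low_income,60-74,786,2514,152,238,349,699,109,75,1.63,1.34,2.33,1.63,1.75,0.36,15.5
3,economic,no_insurance,60-74,453,1517,96,139,679,1688,164,174,1.73,1.21,2.03,1.77,1.68,0.09,4.4
3,economic,renter,60-74,886,2720,165,247,242,463,93,61,1.61,1.40,2.45,1.58,1.80,0.44,17.9
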