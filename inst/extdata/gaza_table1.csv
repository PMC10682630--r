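# Groundwater quality summary, Gaza Strip municipal wells (n = 115, 2022 campaign).
# Columns: per-parameter summary statistics in the declared units, WHO drinking-water
# guideline value (same units), detection limit for censored parameters, censoring mode
# (none / all / point) and the single-well value for point-source detections.
parameter,group,units,max,min,mean,median,sd,who_guideline,guideline_note,detection_limit,censoring,point_value
pH,physical,pH,8.08,6.65,7.45,7.46,0.30,NA,range guideline 6.5-9.5 not representable as a single value,NA,none,NA
EC,physical,uS/cm,29600,709,5202,3750,5101,2000,NA,NA,none,NA
TDS,physical,mg/L,18352,354.5,3261,2325,3187,1000,NA,NA,none,NA
Hardness,physical,mgCaCO3/L,2434,82,467,398,322,200,NA,NA,none,NA
Cl,anion,mg/L,9491,91,1419,810,1797,250,NA,NA,none,NA
NO3,anion,mg/L,365,16,112,93,74,50,NA,NA,none,NA
F,anion,mg/L,2.6,0.2,1.1,1.1,0.53,1.5,NA,NA,none,NA
Br,anion,mg/L,76.5,0.03,3.54,0.25,12.76,2,NA,NA,none,NA
PO4,anion,mg/L,72,72,72,72,NA,NA,single detected well,0.01,point,72
SO4,anion,mg/L,1537,7.8,177,119,199,250,NA,NA,none,NA
HCO3,anion,mg/L,557,132,294,275,87,NA,NA,NA,none,NA
Ca,cation,mg/L,375,13,84,68.4,60,75,NA,NA,none,NA
Mg,cation,mg/L,400,10.7,58,46.8,46,50,NA,NA,none,NA
Na,cation,mg/L,430,22.3,180,176,101,50,NA,NA,none,NA
K,cation,mg/L,48,1.17,7.46,4.82,7.72,12,NA,NA,none,NA
Ag,metal,ug/L,2.1,1.7,1.9,1.9,0.13,100,NA,NA,none,NA
Al,metal,ug/L,NA,NA,NA,NA,NA,200,NA,0.02,all,NA
As,metal,ug/L,NA,NA,NA,NA,NA,10,NA,16,all,NA
Ba,metal,ug/L,417,17.9,146,143,90,1300,NA,NA,none,NA
Cd,metal,ug/L,NA,NA,NA,NA,NA,3,NA,0.3,all,NA
Co,metal,ug/L,NA,NA,NA,NA,NA,20,NA,1.7,all,NA
Cr,metal,ug/L,102,6.9,26,21.3,16.7,50,NA,NA,none,NA
Cu,metal,ug/L,18,18,18,18,NA,2000,single detected well,0.1,point,18
Fe,metal,ug/L,430,0.13,68,87,57,300,NA,NA,none,NA
Mn,metal,ug/L,35.8,0.06,1.56,1.28,3.33,0.8,guideline magnitude as printed is inconsistent with WHO practice for a ug/L row,NA,none,NA
Ni,metal,ug/L,NA,NA,NA,NA,NA,70,NA,15,all,NA
Pb,metal,ug/L,NA,NA,NA,NA,NA,10,NA,3,all,NA
Sr,metal,ug/L,12350,539,2521,1770,2049,NA,no WHO guideline; ATSDR advises 4 mg/L,NA,none,NA
Zn,metal,ug/L,61.2,1.42,9.7,7.59,8.51,3000,NA,NA,none,NA
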