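name,kind,direction,outcome,median,p25,p75,lambda,levels,counts
age,continuous,null,cure,54.5,46.0,65.0,,,
age,continuous,null,improved,55.0,41.0,67.0,,,
age,continuous,null,poor,58.5,47.0,73.0,,,
temperature,continuous,null,cure,36.5,36.4,36.8,,,
temperature,continuous,null,improved,36.7,36.5,36.9,,,
temperature,continuous,null,poor,36.6,36.5,36.8,,,
heart_rate,continuous,risk,cure,85.0,75.5,90.0,,,
heart_rate,continuous,risk,improved,87.5,75.0,102.0,,,
heart_rate,continuous,risk,poor,100.0,78.0,119.0,,,
respiratory_rate,continuous,null,cure,19.0,18.0,20.0,,,
respiratory_rate,continuous,null,improved,20.0,17.0,22.0,,,
respiratory_rate,continuous,null,poor,19.0,16.0,24.0,,,
systolic_bp,continuous,null,cure,127.5,115.5,144.5,,,
systolic_bp,continuous,null,improved,127.5,112.0,144.0,,,
systolic_bp,continuous,null,poor,125.0,98.0,144.0,,,
diastolic_bp,continuous,protective,cure,80.0,71.5,89.0,,,
diastolic_bp,continuous,protective,improved,75.0,65.0,84.0,,,
diastolic_bp,continuous,protective,poor,72.0,57.0,85.0,,,
hb,continuous,protective,cure,121.5,108.0,136.0,,,
hb,continuous,protective,improved,123.0,102.0,135.0,,,
hb,continuous,protective,poor,103.0,81.0,124.0,,,
prothrombin_time,continuous,null,cure,18.5,7.0,36.5,,,
prothrombin_time,continuous,null,improved,22.0,11.0,45.0,,,
prothrombin_time,continuous,null,poor,24.0,10.0,59.0,,,
inr,continuous,null,cure,21.0,8.5,38.5,,,
inr,continuous,null,improved,22.0,8.0,35.0,,,
inr,continuous,null,poor,22.5,9.0,52.0,,,
aptt,continuous,null,cure,49.5,33.0,84.0,,,
aptt,continuous,null,improved,54.5,25.0,84.0,,,
aptt,continuous,null,poor,53.5,19.0,105.0,,,
thrombin_time,continuous,null,cure,28.0,13.5,45.0,,,
thrombin_time,continuous,null,improved,29.5,12.0,49.0,,,
thrombin_time,continuous,null,poor,23.0,10.0,58.0,,,
fibrinogen,continuous,null,cure,86.0,46.0,123.5,,,
fibrinogen,continuous,null,improved,72.0,38.0,127.0,,,
fibrinogen,continuous,null,poor,81.0,29.0,113.0,,,
total_bilirubin,continuous,null,cure,14.4,9.8,20.0,,,
total_bilirubin,continuous,null,improved,13.4,9.4,18.1,,,
total_bilirubin,continuous,null,poor,11.9,8.5,16.1,,,
direct_bilirubin,continuous,null,cure,5.7,3.9,8.2,,,
direct_bilirubin,continuous,null,improved,5.2,3.8,6.8,,,
direct_bilirubin,continuous,null,poor,5.3,3.4,6.7,,,
indirect_bilirubin,continuous,null,cure,8.1,6.0,12.0,,,
indirect_bilirubin,continuous,null,improved,7.9,6.1,11.1,,,
indirect_bilirubin,continuous,null,poor,7.2,5.8,9.2,,,
total_protein,continuous,protective,cure,59.8,55.2,64.8,,,
total_protein,continuous,protective,improved,59.7,52.9,65.3,,,
total_protein,continuous,protective,poor,56.6,47.5,63.0,,,
albumin,continuous,protective,cure,38.1,35.0,41.0,,,
albumin,continuous,protective,improved,38.0,35.1,41.8,,,
albumin,continuous,protective,poor,34.8,29.3,40.0,,,
globulin,continuous,null,cure,21.6,18.2,24.8,,,
globulin,continuous,null,improved,21.3,18.1,24.3,,,
globulin,continuous,null,poor,19.5,16.7,23.5,,,
ag_ratio,continuous,null,cure,1.8,1.5,2.1,,,
ag_ratio,continuous,null,improved,1.8,1.6,2.1,,,
ag_ratio,continuous,null,poor,1.7,1.4,2.0,,,
alt,continuous,null,cure,27.3,18.3,52.4,,,
alt,continuous,null,improved,26.1,16.3,56.6,,,
alt,continuous,null,poor,30.1,18.4,65.5,,,
ast,continuous,risk,cure,32.1,21.9,56.0,,,
ast,continuous,risk,improved,34.4,25.1,61.3,,,
ast,continuous,risk,poor,51.0,31.5,90.5,,,
ast_alt_ratio,continuous,risk,cure,1.3,1.0,1.6,,,
ast_alt_ratio,continuous,risk,improved,1.4,1.1,1.8,,,
ast_alt_ratio,continuous,risk,poor,1.2,1.5,2.1,,,
alp,continuous,null,cure,62.0,50.5,78.0,,,
alp,continuous,null,improved,61.5,50.3,80.0,,,
alp,continuous,null,poor,63.5,46.0,81.0,,,
total_bile_acids,continuous,null,cure,2.7,1.3,5.4,,,
total_bile_acids,continuous,null,improved,2.4,1.1,4.6,,,
total_bile_acids,continuous,null,poor,2.4,0.8,4.4,,,
prealbumin,continuous,protective,cure,250.0,203.0,294.0,,,
prealbumin,continuous,protective,improved,262.5,204.0,294.0,,,
prealbumin,continuous,protective,poor,226.0,134.0,263.0,,,
afu,continuous,null,cure,21.8,18.3,25.9,,,
afu,continuous,null,improved,22.8,18.6,25.7,,,
afu,continuous,null,poor,25.7,17.5,25.7,,,
ada,continuous,protective,cure,7.0,5.0,10.4,,,
ada,continuous,protective,improved,7.0,5.0,10.0,,,
ada,continuous,protective,poor,5.0,5.0,7.6,,,
cholinesterase,continuous,protective,cure,6162,4973,7489,,,
cholinesterase,continuous,protective,improved,5948,4569,7559,,,
cholinesterase,continuous,protective,poor,5305,4569,6507,,,
mito_ast,continuous,null,cure,15.4,9.7,24.3,,,
mito_ast,continuous,null,improved,14.3,9.8,24.3,,,
mito_ast,continuous,null,poor,16.7,9.5,26.6,,,
urea,continuous,null,cure,6.0,4.8,7.3,,,
urea,continuous,null,improved,5.6,4.5,7.1,,,
urea,continuous,null,poor,6.2,4.9,8.0,,,
creatinine,continuous,risk,cure,65.0,57.1,77.5,,,
creatinine,continuous,risk,improved,59.9,50.0,78.3,,,
creatinine,continuous,risk,poor,75.7,54.3,104.3,,,
transfusion_count,count,risk,cure,,,,0.5,,
transfusion_count,count,risk,improved,,,,0.8,,
transfusion_count,count,risk,poor,,,,1.2,,
rescue_count,count,risk,cure,,,,0.05,,
rescue_count,count,risk,improved,,,,0.08,,
rescue_count,count,risk,poor,,,,1.2,,
headache,categorical,risk,cure,,,,,No|Yes|Coma,49|49|10
headache,categorical,risk,improved,,,,,No|Yes|Coma,29|68|33
headache,categorical,risk,poor,,,,,No|Yes|Coma,4|18|32
vomiting,categorical,risk,cure,,,,,No|Yes,88|20
vomiting,categorical,risk,improved,,,,,No|Yes,79|51
vomiting,categorical,risk,poor,,,,,No|Yes,28|26
meningeal_irritation,categorical,null,cure,,,,,No|Yes,104|4
meningeal_irritation,categorical,null,improved,,,,,No|Yes,120|10
meningeal_irritation,categorical,null,poor,,,,,No|Yes,51|3
open_airway,categorical,risk,cure,,,,,No|Yes,97|11
open_airway,categorical,risk,improved,,,,,No|Yes,97|33
open_airway,categorical,risk,poor,,,,,No|Yes,19|35
cranial_pressure_therapy,categorical,risk,cure,,,,,No|Yes,106|2
cranial_pressure_therapy,categorical,risk,improved,,,,,No|Yes,122|8
cranial_pressure_therapy,categorical,risk,poor,,,,,No|Yes,47|7
infection_prophylaxis,categorical,null,cure,,,,,No|Yes,90|18
infection_prophylaxis,categorical,null,improved,,,,,No|Yes,108|22
infection_prophylaxis,categorical,null,poor,,,,,No|Yes,50|4
antishock_therapy,categorical,null,cure,,,,,No|Yes,91|17
antishock_therapy,categorical,null,improved,,,,,No|Yes,106|24
antishock_therapy,categorical,null,poor,,,,,No|Yes,40|14
sex,categorical,null,cure,,,,,Female|Male,21|87
sex,categorical,null,improved,,,,,Female|Male,44|86
sex,categorical,null,poor,,,,,Female|Male,15|39
injury_type,categorical,null,cure,,,,,Traffic|Fall|Other,47|40|21
injury_type,categorical,null,improved,,,,,Traffic|Fall|Other,67|51|12
injury_type,categorical,null,poor,,,,,Traffic|Fall|Other,26|22|6
surgery,categorical,protective,cure,,,,,No|Yes,22|86
surgery,categorical,protective,improved,,,,,No|Yes,42|88
surgery,categorical,protective,poor,,,,,No|Yes,26|28
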