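phase,region,category,increment,unit,unit_cost,maintenance_frac,start_year,end_year
comp,SSA,irrigation_expansion,3.6,Mha,10.484330484330485,0.02,2015,2030
comp,SSA,water_use_efficiency,15.0,efficiency_point,0.373789173789174,0.02,2015,2030
comp,SSA,soil_water_mgmt,33.0,Mha,0.729344729344729,0.02,2015,2030
comp,SSA,infrastructure,1.0,composite_unit,61.811965811965813,0.02,2015,2030
comp,NAWA,irrigation_expansion,1.3,Mha,8.731097961867192,0.02,2015,2030
comp,NAWA,water_use_efficiency,14.0,efficiency_point,0.595848595848596,0.02,2015,2030
comp,NAWA,soil_water_mgmt,4.5,Mha,3.889838556505223,0.02,2015,2030
comp,NAWA,infrastructure,1.0,composite_unit,28.170940170940174,0.02,2015,2030
comp,ODV,irrigation_expansion,12.5,Mha,4.748034188034188,0.02,2015,2030
comp,ODV,water_use_efficiency,15.0,efficiency_point,8.433048433048434,0.02,2015,2030
comp,ODV,soil_water_mgmt,36.0,Mha,1.591642924976258,0.02,2015,2030
comp,ODV,infrastructure,1.0,composite_unit,264.752136752136778,0.02,2015,2030
baseline,SSA,irrigation_expansion,3.0,Mha,17.098360655737704,0.02,2010,2030
baseline,SSA,water_use_efficiency,2.0,efficiency_point,1.118852459016394,0.02,2010,2030
baseline,SSA,soil_water_mgmt,16.0,Mha,0.946721311475410,0.02,2010,2030
baseline,SSA,infrastructure,1.0,composite_unit,2.926229508196722,0.02,2010,2030
baseline,NAWA,irrigation_expansion,3.0,Mha,4.647540983606557,0.02,2010,2030
baseline,NAWA,water_use_efficiency,2.0,efficiency_point,0.602459016393443,0.02,2010,2030
baseline,NAWA,soil_water_mgmt,12.0,Mha,0.918032786885246,0.02,2010,2030
baseline,NAWA,infrastructure,1.0,composite_unit,15.491803278688527,0.02,2010,2030
baseline,ODV,irrigation_expansion,12.0,Mha,5.407786885245901,0.02,2010,2030
baseline,ODV,water_use_efficiency,2.4,efficiency_point,14.487704918032788,0.02,2010,2030
baseline,ODV,soil_water_mgmt,40.0,Mha,0.903688524590164,0.02,2010,2030
baseline,ODV,infrastructure,1.0,composite_unit,421.721311475409834,0.02,2010,2030
baseline,DEV,irrigation_expansion,2.0,Mha,4.819672131147541,0.02,2010,2030
baseline,DEV,water_use_efficiency,1.0,efficiency_point,2.926229508196722,0.02,2010,2030
baseline,DEV,infrastructure,1.0,composite_unit,463.377049180327901,0.02,2010,2030
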