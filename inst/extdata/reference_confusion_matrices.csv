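"source","truth","predicted","count"
"rater1","none","none",26
"rater1","none","mild",5
"rater1","none","moderate_severe",0
"rater1","mild","none",0
"rater1","mild","mild",19
"rater1","mild","moderate_severe",2
"rater1","moderate_severe","none",0
"rater1","moderate_severe","mild",2
"rater1","moderate_severe","moderate_severe",4
"rater2","none","none",25
"rater2","none","mild",7
"rater2","none","moderate_severe",0
"rater2","mild","none",4
"rater2","mild","mild",18
"rater2","mild","moderate_severe",2
"rater2","moderate_severe","none",0
"rater2","moderate_severe","mild",0
"rater2","moderate_severe","moderate_severe",6
"rater3","none","none",31
"rater3","none","mild",0
"rater3","none","moderate_severe",0
"rater3","mild","none",1
"rater3","mild","mild",24
"rater3","mild","moderate_severe",5
"rater3","moderate_severe","none",1
"rater3","moderate_severe","mild",2
"rater3","moderate_severe","moderate_severe",3
"rater4","none","none",20
"rater4","none","mild",11
"rater4","none","moderate_severe",1
"rater4","mild","none",2
"rater4","mild","mild",11
"rater4","mild","moderate_severe",7
"rater4","moderate_severe","none",0
"rater4","moderate_severe","mild",0
"rater4","moderate_severe","moderate_severe",3
"pooled_raters","none","none",102
"pooled_raters","none","mild",23
"pooled_raters","none","moderate_severe",1
"pooled_raters","mild","none",7
"pooled_raters","mild","mild",72
"pooled_raters","mild","moderate_severe",16
"pooled_raters","moderate_severe","none",1
"pooled_raters","moderate_severe","mild",4
"pooled_raters","moderate_severe","moderate_severe",16
"svm_poly","none","none",74
"svm_poly","none","mild",35
"svm_poly","none","moderate_severe",1
"svm_poly","mild","none",34
"svm_poly","mild","mild",54
"svm_poly","mild","moderate_severe",11
"svm_poly","moderate_severe","none",8
"svm_poly","moderate_severe","mild",16
"svm_poly","moderate_severe","moderate_severe",9
"ordinal_regression","none","none",77
"ordinal_regression","none","mild",31
"ordinal_regression","none","moderate_severe",2
"ordinal_regression","mild","none",30
"ordinal_regression","mild","mild",59
"ordinal_regression","mild","moderate_severe",10
"ordinal_regression","moderate_severe","none",9
"ordinal_regression","moderate_severe","mild",14
"ordinal_regression","moderate_severe","moderate_severe",10
"knn","none","none",83
"knn","none","mild",27
"knn","none","moderate_severe",0
"knn","mild","none",28
"knn","mild","mild",63
"knn","mild","moderate_severe",8
"knn","moderate_severe","none",4
"knn","moderate_severe","mild",22
"knn","moderate_severe","moderate_severe",7
"random_forest","none","none",80
"random_forest","none","mild",29
"random_forest","none","moderate_severe",1
"random_forest","mild","none",26
"random_forest","mild","mild",63
"random_forest","mild","moderate_severe",10
"random_forest","moderate_severe","none",3
"random_forest","moderate_severe","mild",20
"random_forest","moderate_severe","moderate_severe",10
"ensemble","none","none",23
"ensemble","none","mild",87
"ensemble","none","moderate_severe",0
"ensemble","mild","none",4
"ensemble","mild","mild",94
"ensemble","mild","moderate_severe",1
"ensemble","moderate_severe","none",2
"ensemble","moderate_severe","mild",26
"ensemble","moderate_severe","moderate_severe",5
"f0_sd_only","none","none",14
"f0_sd_only","none","mild",0
"f0_sd_only","none","moderate_severe",96
"f0_sd_only","mild","none",21
"f0_sd_only","mild","mild",0
"f0_sd_only","mild","moderate_severe",78
"f0_sd_only","moderate_severe","none",4
"f0_sd_only","moderate_severe","mild",0
"f0_sd_only","moderate_severe","moderate_severe",28
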