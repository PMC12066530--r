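"source","metric","value"
"rater1","sensitivity",0.8
"rater1","specificity",0.92
"rater1","ppv",0.8
"rater1","npv",0.91
"rater1","balanced_accuracy",0.86
"rater1","f_score",0.8
"rater2","sensitivity",0.84
"rater2","specificity",0.88
"rater2","ppv",0.78
"rater2","npv",0.88
"rater2","balanced_accuracy",0.86
"rater2","f_score",0.8
"rater3","sensitivity",0.77
"rater3","specificity",0.94
"rater3","ppv",0.75
"rater3","npv",0.93
"rater3","balanced_accuracy",0.85
"rater3","f_score",0.75
"rater4","sensitivity",0.73
"rater4","specificity",0.81
"rater4","ppv",0.56
"rater4","npv",0.79
"rater4","balanced_accuracy",0.77
"rater4","f_score",0.56
"pooled_raters","sensitivity",0.78
"pooled_raters","specificity",0.89
"pooled_raters","ppv",0.71
"pooled_raters","npv",0.88
"pooled_raters","balanced_accuracy",0.83
"pooled_raters","f_score",0.73
"svm_poly","sensitivity",0.5
"svm_poly","specificity",0.76
"svm_poly","ppv",0.53
"svm_poly","npv",0.76
"svm_poly","balanced_accuracy",0.63
"svm_poly","f_score",0.51
"ordinal_regression","sensitivity",0.53
"ordinal_regression","specificity",0.78
"ordinal_regression","ppv",0.56
"ordinal_regression","npv",0.78
"ordinal_regression","balanced_accuracy",0.66
"ordinal_regression","f_score",0.54
"knn","sensitivity",0.53
"knn","specificity",0.79
"knn","ppv",0.58
"knn","npv",0.8
"knn","balanced_accuracy",0.66
"knn","f_score",0.54
"random_forest","sensitivity",0.56
"random_forest","specificity",0.8
"random_forest","ppv",0.59
"random_forest","npv",0.8
"random_forest","balanced_accuracy",0.68
"random_forest","f_score",0.57
"ensemble","sensitivity",0.44
"ensemble","specificity",0.72
"ensemble","ppv",0.69
"ensemble","npv",0.78
"ensemble","balanced_accuracy",0.58
"ensemble","f_score",0.4
"f0_sd_only","sensitivity",0.33
"f0_sd_only","specificity",0.65
"f0_sd_only","ppv",NA
"f0_sd_only","npv",0.67
"f0_sd_only","balanced_accuracy",0.49
"f0_sd_only","f_score",0.2
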