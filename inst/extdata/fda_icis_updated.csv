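trial_id,indication_id,drug,cancer_type,year_approved,setting,endpoint,hr,ci_lower,ci_upper,ci_level,median_control,median_experimental,toxicity_points_override,tail_bonus_override,landmark_gain_qualifies,qol,toxicity_reduced,palliation_improved,tfi_improved,toxic_death_increased,assessment_phase,exp_treatment_effect,exp_toxicity,exp_tail,exp_palliation,exp_qol,exp_tfi,exp_nhb,exp_esmo_grade,exp_long_term
PACIFIC,PACIFIC,Durvalumab,NSCLC,2018,non_curative,OS,0.68,0.47,0.997,99.73,,,-6.2,16,FALSE,not_reported,FALSE,FALSE,FALSE,FALSE,updated,32,-6.2,16,0,0,0,41.8,4,FALSE
OAK,OAK,Atezolizumab,NSCLC,2016,non_curative,OS,0.75,0.64,0.89,95,,,2.7,0,FALSE,not_improved,TRUE,TRUE,FALSE,FALSE,updated,25,2.7,0,10,0,0,37.7,5,FALSE
KEYNOTE-45,KEYNOTE-45,Pembrolizumab,Urothelial carcinoma,2017,non_curative,OS,0.73,0.59,0.91,95,,,1.0,20,FALSE,improved,TRUE,TRUE,FALSE,FALSE,updated,27,1.0,20,10,10,0,68.0,4,FALSE
KEYNOTE-24,KEYNOTE-24,Pembrolizumab,NSCLC,2017,non_curative,OS,0.60,0.41,0.89,95,,,5.9,0,FALSE,improved,TRUE,TRUE,FALSE,FALSE,updated,40,5.9,0,10,10,0,65.9,5,FALSE
KEYNOTE-006-1,KEYNOTE-006,Pembrolizumab,Melanoma,2015,non_curative,OS,0.68,0.53,0.87,95,,,2.3,16,FALSE,improved,FALSE,FALSE,FALSE,FALSE,updated,32,2.3,16,0,10,0,60.3,5,FALSE
KEYNOTE-006-2,KEYNOTE-006,Pembrolizumab,Melanoma,2015,non_curative,OS,0.68,0.53,0.86,95,,,3.1,16,FALSE,improved,FALSE,FALSE,FALSE,FALSE,updated,32,3.1,16,0,10,0,61.1,5,FALSE
CHECKMATE-141,CHECKMATE-141,Nivolumab,SCCHN,2016,non_curative,OS,0.68,0.54,0.86,95,,,7.1,20,TRUE,improved,TRUE,TRUE,FALSE,FALSE,updated,32,7.1,20,10,10,0,79.1,5,FALSE
CHECKMATE-025,CHECKMATE-025,Nivolumab,RCC,2015,non_curative,OS,0.73,0.57,0.93,98.5,,,6.8,0,FALSE,improved,TRUE,TRUE,FALSE,FALSE,updated,27,6.8,0,10,10,0,53.8,5,FALSE
CHECKMATE-017,CHECKMATE-017,Nivolumab,NSCLC,2015,non_curative,OS,0.62,0.48,0.80,95,,,11.3,20,FALSE,improved,TRUE,TRUE,FALSE,FALSE,updated,38,11.3,20,10,10,0,89.3,5,FALSE
CHECKMATE-057,CHECKMATE-057,Nivolumab,NSCLC,2015,non_curative,OS,0.73,0.62,0.88,95,,,8.3,20,FALSE,improved,TRUE,TRUE,FALSE,FALSE,updated,27,8.3,20,10,10,0,75.3,5,FALSE
CHECKMATE-066,CHECKMATE-066,Nivolumab,Melanoma,2015,non_curative,OS,0.42,0.25,0.73,99.79,,,2.4,16,FALSE,improved,FALSE,FALSE,FALSE,FALSE,updated,58,2.4,16,0,10,0,86.4,5,FALSE
CHECKMATE-067-1,CHECKMATE-067,Nivolumab plus ipilimumab,Melanoma,2015,non_curative,OS,0.54,0.44,0.67,95,,,-9.0,20,FALSE,not_improved,FALSE,FALSE,TRUE,TRUE,updated,46,-9.0,20,0,0,10,67.0,3,FALSE
CHECKMATE-067-2,CHECKMATE-067,Nivolumab,Melanoma,2015,non_curative,OS,0.65,0.53,0.79,95,,,0.3,20,FALSE,not_improved,FALSE,FALSE,FALSE,FALSE,updated,35,0.3,20,0,0,0,55.3,4,FALSE
KEYNOTE-002-1,KEYNOTE-002,Pembrolizumab,Melanoma,2015,non_curative,PFS,0.57,0.45,0.73,95,,,5.4,16,TRUE,improved,TRUE,TRUE,FALSE,FALSE,updated,34.4,5.4,16,10,10,0,75.8,4,TRUE
KEYNOTE-002-2,KEYNOTE-002,Pembrolizumab,Melanoma,2015,non_curative,PFS,0.50,0.39,0.64,95,,,4.4,16,TRUE,improved,TRUE,TRUE,FALSE,FALSE,updated,40,4.4,16,10,10,0,80.4,4,TRUE
EORTC-18071,EORTC-18071,Ipilimumab,Melanoma,2015,curative,OS,0.72,0.58,0.88,95,,,-8.5,0,FALSE,not_improved,FALSE,FALSE,FALSE,FALSE,updated,28,-8.5,0,0,0,0,19.5,A,FALSE
MDX010-20-1,MDX010-20,Ipilimumab,Melanoma,2011,non_curative,OS,0.66,0.51,0.87,95,,,1.0,20,FALSE,not_improved,FALSE,FALSE,FALSE,FALSE,updated,34,1.0,20,0,0,0,55.0,4,FALSE
MDX010-20-2,MDX010-20,Ipilimumab plus gp100,Melanoma,2011,non_curative,OS,0.68,0.55,0.85,95,,,-0.3,20,FALSE,not_improved,FALSE,FALSE,FALSE,FALSE,updated,32,-0.3,20,0,0,0,51.7,4,FALSE
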