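id,label,cluster,count,prevalence_pct,severity_mean,severity_sd
dizziness,Faintness or dizziness,somatization,194,38.6,0.50,0.73
chest_pain,Pain in the heart or chest,somatization,136,27.0,0.34,0.63
nausea,Nausea or upset stomach,somatization,89,17.7,0.23,0.56
breathlessness,Trouble catching your breath,somatization,152,30.2,0.41,0.71
hot_cold_spells,Hot or cold spells,somatization,163,32.6,0.45,0.73
numbness,Numbness or tingling in parts of your body,somatization,201,40.0,0.53,0.75
weakness,Feeling weak in parts of your body,somatization,358,71.2,1.02,0.85
concentration,Difficulty concentrating,cognitive_function,258,51.3,0.75,0.86
forgetfulness,Forgetting things that occurred recently,cognitive_function,330,65.6,0.94,0.86
reasoning,Difficulty reasoning,cognitive_function,186,37.0,0.50,0.76
confusion,Becoming confused,cognitive_function,183,36.4,0.52,0.79
slow_reactions,Having slow reactions,cognitive_function,282,56.1,0.77,0.81
distressed,Distressed,negative_affect,206,41.0,0.63,0.89
upset,Upset,negative_affect,284,56.5,0.84,0.91
guilty,Guilty,negative_affect,224,44.5,0.71,0.94
scared,Scared,negative_affect,233,46.3,0.72,0.92
hostile,Hostile,negative_affect,148,29.4,0.42,0.75
irritable,Irritable,negative_affect,268,53.3,0.81,0.91
ashamed,Ashamed,negative_affect,183,36.4,0.56,0.88
nervous,Nervous,negative_affect,296,58.8,0.88,0.91
jittery,Jittery,negative_affect,269,53.5,0.81,0.92
afraid,Afraid,negative_affect,233,46.3,0.72,0.92
feelings_hurt,Your feelings are easily hurt,interpersonal,234,46.5,0.66,0.83
people_unfriendly,Feeling that people are unfriendly or dislike you,interpersonal,178,35.4,0.47,0.74
inferiority,Feeling inferior to others,interpersonal,227,45.1,0.68,0.90
self_conscious,Feeling very self-conscious around others,interpersonal,232,46.1,0.65,0.84
future_uncertainty,Uncertainty about the future,cognitive_processes,322,64.0,1.07,1.01
future_discouraged,Feeling discouraged about the future,cognitive_processes,247,49.1,0.79,0.96
punishment_belief,The belief that I should be punished for my sins,cognitive_processes,148,29.4,0.44,0.79
low_confidence,Lack of confidence around others,cognitive_processes,216,42.9,0.65,0.88
feeling_watched,Feeling that I am being watched or talked about by others,cognitive_processes,145,28.8,0.39,0.70
worthlessness,Feelings of worthlessness,cognitive_processes,203,40.4,0.61,0.87
suicidal_ideas,Suicidal ideas,cognitive_processes,156,31.0,0.49,0.85
escaping_reality,Escaping from reality,social_adaptation,212,42.1,0.63,0.87
social_withdrawal,Unable to integrate into society,social_adaptation,154,30.6,0.46,0.80
daily_impairment,Unable to handle daily work and study,social_adaptation,120,23.9,0.34,0.69
sleep_disturbance,Sleep disturbance,,298,59.2,0.92,0.93
loneliness,Loneliness,,285,56.7,0.90,0.98
sadness,Sadness,,240,47.7,0.78,0.98
anger,Anger,,189,37.6,0.56,0.85
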