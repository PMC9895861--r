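cluster,count,prevalence_pct,severity_mean,severity_sd,cronbach_alpha
somatization,394,78.5,3.49,3.72,0.868
cognitive_function,363,72.2,3.48,3.55,0.921
negative_affect,382,75.9,7.25,7.54,0.953
interpersonal,303,60.2,2.45,2.90,0.899
cognitive_processes,351,69.8,4.45,5.04,0.915
social_adaptation,231,45.9,1.43,2.13,0.880
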