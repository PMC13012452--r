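{"id":"dx-ratio-lln","text":"Airflow obstruction is established when the measured FEV1/FVC ratio falls below its lower limit of normal; the ratio-versus-LLN comparison is the primary diagnostic criterion and precedes any interpretation of individual volumes.","tags":["diagnosis","lln"],"source":"spirokit paraphrase"}
{"id":"dx-scooped","text":"A concave or scooped descending limb of the flow-volume curve indicates disproportionate flow loss at mid and low lung volumes and supports small-airway obstruction even when volumes are preserved.","tags":["diagnosis","morphology"],"source":"spirokit paraphrase"}
{"id":"sev-grades","text":"Once obstruction is confirmed, severity is graded by FEV1 percent predicted: grade 1 mild at 80 percent or more, grade 2 moderate 50 to 79 percent, grade 3 severe 30 to 49 percent, grade 4 very severe below 30 percent.","tags":["severity","grading"],"source":"spirokit paraphrase"}
{"id":"sev-followup","text":"Moderate and worse airflow obstruction severity warrants periodic spirometric follow-up and assessment of symptom burden and exacerbation history.","tags":["severity","monitoring"],"source":"spirokit paraphrase"}
{"id":"tx-smoking","text":"Smoking cessation is the single most effective intervention to slow decline of lung function in obstructive airway disease and should be offered at every encounter for current smokers.","tags":["treatment","smoking"],"source":"spirokit paraphrase"}
{"id":"tx-bronchodilator","text":"Inhaled bronchodilator therapy is the cornerstone of symptomatic treatment of confirmed airflow obstruction, escalated according to symptom burden and exacerbation risk.","tags":["treatment","pharmacotherapy"],"source":"spirokit paraphrase"}
{"id":"tx-rehab","text":"Pulmonary rehabilitation and vaccination against respiratory pathogens reduce symptom burden and exacerbation risk in moderate to very severe disease.","tags":["treatment","rehabilitation"],"source":"spirokit paraphrase"}
{"id":"normal-reassure","text":"When the FEV1/FVC ratio is at or above its lower limit of normal and the curve morphology is linear or convex, spirometry does not support airflow obstruction; isolated reductions below predicted values should not be over-read.","tags":["diagnosis","normal"],"source":"spirokit paraphrase"}
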