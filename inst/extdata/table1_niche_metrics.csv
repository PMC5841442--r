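trophic_category,reef,NR,CR,TA,SEA,SEAc,overlap_area,overlap_pct_printed
herbivore,coral_dominated,4.88,2.80,6.06,2.54,2.75,2.42,88
herbivore,degraded,4.59,6.58,11.00,4.75,5.15,2.42,47
omnivore,coral_dominated,6.12,6.31,24.56,8.33,8.82,8.78,100
omnivore,degraded,6.01,7.55,32.02,10.01,10.60,8.78,84
carnivore,coral_dominated,4.36,3.75,7.45,3.03,3.26,2.25,69
carnivore,degraded,5.38,2.39,6.93,2.76,2.97,2.25,76
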