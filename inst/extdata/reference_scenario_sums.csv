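# Reference scenario summary from the original clinical study cohort
# (43 idiopathic hypersomnia patients): per-aggregate signed simulation
# output sums (dimensionless), published absolute contribution percentages,
# and Mann-Whitney p-values comparing the last-5-years and medicated-only
# scenarios. Decimal commas in the source converted to points.
aggregate,baseline_sum,baseline_pct,last5_sum,last5_pct,medicated_sum,medicated_pct,p_value
Anxiety,-5264.94,4.6,-7695.29,5.1,-2127.76,6.3,0.111
Depression,-1468.65,1.3,-1936.36,1.3,-519.98,1.5,0.345
Sleep inertia,-23785.71,20.7,-31467.42,20.8,-7561.71,22.3,0.48
Work and social impairment,-19854.40,17.3,-22906.08,15.2,-2865.86,8.5,0.004
Sleepiness,-12983.30,11.3,-17127.30,11.3,-3760.46,11.1,0.028
Fatigue,-5885.17,5.1,-9196.22,6.1,-3168.03,9.3,0.345
Naps,19689.76,17.2,26442.19,17.5,5941.81,17.5,0.028
Nocturnal sleep,17099.39,14.9,22418.76,14.8,4535.73,13.4,0.008
Other psychiatric disorders,-1502.53,1.3,-1954.41,1.3,-550.40,1.6,0.345
Somatic pathologies,-4773.05,4.2,-5924.73,3.9,-1077.70,3.2,0.004
Methylphenidate effect,1109.83,1.0,1768.80,1.2,782.93,2.3,0.421
Modafinil effect,1254.81,1.1,2244.32,1.5,1014.49,3.0,0.5
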