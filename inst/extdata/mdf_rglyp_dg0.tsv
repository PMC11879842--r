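# Transformed standard reaction Gibbs energies for the rGlyP route,
# formate -> pyruvate, including the NADH-regenerating formate
# dehydrogenase. Reconstructed component-contribution-style estimates at
# pH 7.5, I = 0.25 M, 1 mM Mg2+ (the paper's per-reaction values are not
# printed; these fixtures support property- and oracle-based checks only).
reaction_id	equation	dg0_prime_kj_mol	ph	ionic_strength_M	mg_M	provenance
FDH	for + nad = co2 + nadh	-16.5	7.5	0.25	0.001	reconstructed
FTL	for + thf + atp = f10thf + adp + pi	-4.1	7.5	0.25	0.001	reconstructed
FCH	f10thf + h = methenylthf + h2o	-2.5	7.5	0.25	0.001	reconstructed
MTD	methenylthf + nadph = mlthf + nadp	-12.0	7.5	0.25	0.001	reconstructed
GCS	mlthf + co2 + nh4 + nadh = gly + thf + nad	12.8	7.5	0.25	0.001	reconstructed
SHMT	gly + mlthf + h2o = ser + thf	-6.0	7.5	0.25	0.001	reconstructed
SDA	ser = pyr + nh4	-19.6	7.5	0.25	0.001	reconstructed
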