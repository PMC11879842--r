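# Transformed standard reaction Gibbs energies for the Calvin-cycle route,
# formate -> pyruvate (formate oxidation supplies NADH; GAPDH is
# NAD+-dependent). Reconstructed component-contribution-style estimates at
# pH 7.5, I = 0.25 M, 1 mM Mg2+; property/oracle checks only.
reaction_id	equation	dg0_prime_kj_mol	ph	ionic_strength_M	mg_M	provenance
FDH	for + nad = co2 + nadh	-16.5	7.5	0.25	0.001	reconstructed
RBPC	rubp + co2 + h2o = 2 pg3 + 2 h	-34.0	7.5	0.25	0.001	reconstructed
PGK	pg3 + atp = bpg13 + adp	18.8	7.5	0.25	0.001	reconstructed
GAPDH	bpg13 + nadh + h = g3p + nad + pi	-5.9	7.5	0.25	0.001	reconstructed
TPI	g3p = dhap	-5.5	7.5	0.25	0.001	reconstructed
FBA	g3p + dhap = fbp	-20.6	7.5	0.25	0.001	reconstructed
FBP	fbp + h2o = f6p + pi	-10.6	7.5	0.25	0.001	reconstructed
TKT1	f6p + g3p = xu5p + e4p	3.8	7.5	0.25	0.001	reconstructed
SBA	e4p + dhap = sbp	-19.7	7.5	0.25	0.001	reconstructed
SBP	sbp + h2o = s7p + pi	-10.1	7.5	0.25	0.001	reconstructed
TKT2	s7p + g3p = r5p + xu5p	3.3	7.5	0.25	0.001	reconstructed
RPI	r5p = ru5p	2.2	7.5	0.25	0.001	reconstructed
RPE	xu5p = ru5p	1.0	7.5	0.25	0.001	reconstructed
PRK	ru5p + atp = rubp + adp + h	-15.3	7.5	0.25	0.001	reconstructed
PGM	pg3 = pg2	4.2	7.5	0.25	0.001	reconstructed
ENO	pg2 = pep + h2o	-3.8	7.5	0.25	0.001	reconstructed
PYK	pep + adp + h = pyr + atp	-27.0	7.5	0.25	0.001	reconstructed
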