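# calfcontrib default reduced calf model (synthetic surrogate parameters).
# Sign convention: dorsiflexion, inversion and toe (MTP) extension positive.
# f_max and moment arms are literature-typical configurable priors, not
# measurements; all values may be overridden by supplying another model file.
# Units: f_max_N in newtons, moment arms in metres, anthropometry in
# body-mass fractions and metres.
[dofs]
ankle_flexion
subtalar
mtp_flexion
[muscles]
muscle	group	f_max_N	r_ankle_m	r_subtalar_m	r_mtp_m
Tibialis anterior	dorsiflexor	1100	0.045	0.012	0
Extensor hallucis longus	toe_extensor	250	0.030	0.004	0.020
Extensor digitorum longus 1st	toe_extensor	150	0.030	-0.006	0.018
Extensor digitorum longus 2nd	toe_extensor	150	0.030	-0.006	0.018
Extensor digitorum longus 3rd	toe_extensor	150	0.030	-0.006	0.018
Fibularis peroneus brevis	evertor	350	-0.010	-0.030	0
Gastrocnemius lateralis	plantarflexor	700	-0.050	-0.008	0
Gastrocnemius medialis	plantarflexor	1500	-0.050	0.002	0
Soleus	plantarflexor	4000	-0.050	0.004	0
Flexor hallucis longus	toe_flexor	450	-0.025	0.012	-0.016
Flexor digitorum longus 1st	toe_flexor	120	-0.020	0.012	-0.012
Flexor digitorum longus 2nd	toe_flexor	120	-0.020	0.012	-0.012
Flexor digitorum longus 3rd	toe_flexor	120	-0.020	0.012	-0.012
Tibialis posterior 1st	invertor	400	-0.015	0.028	0
Tibialis posterior 2nd	invertor	400	-0.015	0.028	0
Tibialis posterior 3rd	invertor	400	-0.015	0.028	0
Tibialis posterior 4th	invertor	400	-0.015	0.028	0
[segments]
segment	mass_fraction	com_offset_m	gyration_radius_m
foot	0.0145	0.050	0.069
shank	0.0465	0.190	0.100
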