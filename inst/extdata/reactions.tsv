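# Mass-action reaction table for the water-radiolysis / lipid-peroxidation network.
# One row per reaction. 'k' is the event-rate constant: the reaction rate is
#   r = k * [A] * [B]      (order 2; for self-reactions r = k * [A]^2, and each
#                           event consumes two molecules of A)
#   r = k * [A]            (order 1; radical decay channels and the
#                           hydrogen-peroxide disproportionation channel)
# Units: order-2 constants are M^-1 s^-1, order-1 constants are s^-1.
# Constant-pool reactants (H2O, RH, LH, Hp, OHm, Fe2) are folded into an
# effective pseudo-first-order constant when the network is built.
# 'flag' marks reactions that are switchable at build time.
#
# Two lipid-phase constants are calibrated rather than tabulated (see the
# methods vignette): 'roo_decay' is the effective first-order conversion of
# peroxyl radicals to the hydroperoxide through antioxidant H-donation
# (0.1092 1/s; together with the 0.0408 1/s pseudo-first-order propagation
# channel roo_lh x [LH] this sets a ~6.7 s peroxyl lifetime), and 'roo_roo'
# is the bimolecular peroxyl-peroxyl termination (Russell mechanism, no
# hydroperoxide produced) whose competition with the first-order channels
# is the dose-rate-sparing mechanism.
id	reactants	products	k	order	flag
e_hydrolysis	e + H2O	H + OHm	1.9e1	2
e_e	e + e	H2 + 2 OHm	5.5e9	2
e_h	e + H	H2 + OHm	2.5e10	2
e_oh	e + OH	OHm	3.0e10	2
e_om	e + Om	2 OHm	2.2e10	2
e_hplus	e + Hp	H	2.3e10	2
e_h2o2	e + H2O2	OH + OHm	1.1e10	2
e_ho2m	e + HO2m	OH + 2 OHm	3.5e9	2
e_o2	e + O2	O2m	1.9e10	2
e_o2m	e + O2m	HO2m	1.3e10	2
h_ohm	H + OHm	e	2.2e7	2
e_rh	e + RH	RHm	1.4e8	2
h_o2	H + O2	O2m	2.1e10	2
oh_o2m	OH + O2m	OHm + O2	8.0e9	2
om_o2	Om + O2	O3m	3.6e9	2
om_o2m	Om + O2m	2 OHm + O2	6.0e8	2
o2m_o2m	O2m + O2m	H2O2 + O2	2.0e9	2
r_o2	R + O2	ROO	5.0e7	2
roo_roo	ROO + ROO	O2 + ROX	2.0e4	2
h2o2_disprop	H2O2 + H2O2	O2	6.62e7	1	h2o2_disprop
h_h2o2	H + H2O2	OH	9.0e7	2
h_ho2	H + O2m	H2O2	1.0e10	2
oh_oh	OH + OH	H2O2	5.5e9	2
oh_ho2m	OH + HO2m	OHm + O2m	7.5e9	2
fenton	Fe2 + H2O2	OH + OHm	1.0e3	2
h_h2o	H + H2O	H2 + OH	1.0e1	2
h_oh	H + OH	H2O	7.0e9	2
oh_h2	OH + H2	H	4.2e7	2
oh_ohm	OH + OHm	Om	1.3e10	2
om_h2o	Om + H2O	OHm + OH	1.8e6	2
oh_rh	OH + RH	R	1.0e9	2
oh_gsh	OH + GSH	GS	1.0e10	2
h_h	H + H	H2	7.75e9	2
h_rh	H + RH	RH2	1.0e8	2
roo_lh	ROO + LH	ROOH + L	2.0e1	2
r_decay	R		3.0e2	1
r_r	R + R	RR	2.5e7	2
roo_decay	ROO	ROOH	1.092e-1	1
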