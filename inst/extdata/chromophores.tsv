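chromophore	wavelength_nm	mua_per_unit_fraction_mm1	source
water	900	0.0068	Hale & Querry 1973 / Segelstein 1981 compilation
water	930	0.0135	Hale & Querry 1973 / Segelstein 1981 compilation
water	970	0.0440	Hale & Querry 1973 / Segelstein 1981 compilation
water	980	0.0465	Hale & Querry 1973 / Segelstein 1981 compilation
water	1200	0.1040	Segelstein 1981 compilation
water	1300	0.1350	Segelstein 1981 compilation
lipid	900	0.0012	van Veen et al. 2005 (soybean oil)
lipid	930	0.0107	van Veen et al. 2005 (soybean oil)
lipid	970	0.0046	van Veen et al. 2005 (soybean oil)
lipid	980	0.0042	van Veen et al. 2005 (soybean oil)
lipid	1200	0.1100	van Veen et al. 2005 (soybean oil, 1211 nm band)
lipid	1300	0.0200	van Veen et al. 2005 (soybean oil)
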