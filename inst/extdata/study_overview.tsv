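study	phase	individuals	samples	responders	nonresponders
Frankel2017	discovery	39	39	19	20
Gopalakrishnan2018	discovery	25	25	14	11
Matson2018	discovery	38	38	14	24
Baruch2021	fmt	10	42	3	7
Davar2021	fmt	15	214	3	12
Spencer2021	validation	158	158	100	58
Lee2022	validation	164	164	100	64
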