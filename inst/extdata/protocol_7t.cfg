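# 7T MP2RAGE study protocol (SI units: seconds, degrees)
tr_mp2rage = 8.5
ti1 = 1.0
ti2 = 3.0
alpha1 = 5
alpha2 = 5
n_exc = 252
tr_gre = 0.0069
inv_eff = 1.0
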