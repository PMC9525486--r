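# Decay scheme: Lu-177 (beta-minus emitter)
# Source: compiled from public nuclear-data evaluations (ICRP-107-class / ENSDF-class);
#   conversion-electron and Auger lines are grouped approximations of the full listing.
# Gamma and X-ray emissions are intentionally omitted: photons are not transported.
# record types:
#   H <half_life_days>
#   B <endpoint_MeV> <yield_per_decay> <daughter_Z>     beta-minus branch
#   E <energy_MeV> <yield_per_decay>                    discrete electron (CE/Auger)
# version: 1
H 6.647
B 0.49830 0.793 72
B 0.38480 0.090 72
B 0.24850 0.002 72
B 0.17650 0.115 72
E 0.04760 0.097
E 0.11040 0.030
E 0.14510 0.010
E 0.00690 0.120
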