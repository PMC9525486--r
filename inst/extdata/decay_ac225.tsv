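# Decay scheme: Ac-225 alpha chain, terminated at Pb-209 -> Bi-209
#   Ac-225 -> Fr-221 -> At-217 -> Bi-213 -(97.8% beta)-> Po-213 -> Pb-209
#                                 Bi-213 -(2.2% alpha)-> Tl-209 -> Pb-209
# Source: compiled from public nuclear-data evaluations (ICRP-107-class / ENSDF-class);
#   minor alpha lines are grouped into the dominant ones so that per-nuclide yields
#   sum to 1. Gammas/X-rays omitted (not transported). Recoil nuclei are deposited
#   locally; recoil energy is E_alpha * 4 / A_daughter.
# record types:
#   H <half_life_days>
#   P <bi213_alpha_branch_probability>
#   A <emitting_nuclide> <energy_MeV> <yield_within_nuclide> <branch: main|bi213alpha|bi213beta> <A_daughter>
#   B <emitting_nuclide> <endpoint_MeV> <yield_within_nuclide> <daughter_Z> <branch: main|bi213alpha|bi213beta>
# version: 1
H 9.920
P 0.0220
A Ac-225 5.830 0.507 main 221
A Ac-225 5.793 0.241 main 221
A Ac-225 5.732 0.252 main 221
A Fr-221 6.341 0.833 main 217
A Fr-221 6.243 0.013 main 217
A Fr-221 6.126 0.154 main 217
A At-217 7.067 1.000 main 213
A Bi-213 5.875 1.000 bi213alpha 209
A Po-213 8.376 1.000 bi213beta 209
B Bi-213 1.4230 0.663 84 bi213beta
B Bi-213 0.9830 0.314 84 bi213beta
B Bi-213 0.3200 0.023 84 bi213beta
B Tl-209 1.8300 1.000 82 bi213alpha
B Pb-209 0.6440 1.000 83 main
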