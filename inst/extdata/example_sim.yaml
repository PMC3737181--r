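# Simulated purine-selection screen of ry606N / ry609N heteroallelic females.
# Event rate and tract scale are set to the magnitudes observed in real
# screens (total recombinant rate of order 4-5 per 10^5 progeny; mean
# conversion tract of order 800 bp).
n_progeny: 1000000
event_rate: 6.0e-5
p_co: 0.5
mean_tract_bp: 800
dsb_window: [-3149, 6998]
location_label: 6E
seed: 1
selection_recovery: 2
bottles_per_tray: 25
trays: NA
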