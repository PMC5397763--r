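# interlock demo configuration: desk-scale synthetic study with one planted
# inter-domain coupling, a planted communication path and a partially broken
# interface. All values shown are the documented defaults.

[run]
seed = 1
outdir = interlock_out

[simulate]
n_seqs = 100
length_a = 60
length_b = 60
coupling_i = 10
coupling_j = 80
coupling_strength = 0.9
gap_fraction = 0.05
n_res_a = 12
n_res_b = 12
contact_pairs = 3:4,6:7
hbond_pairs = 3:4
path_chain = 2,5,8,11
n_frames = 10
noise_sd = 0.05
broken_fraction = 0.2

[coevolve]
a = 0.05
b = 10
top_n = 24
min_separation = 5
max_gap_fraction = 0.30

[psn]
i_min = auto
contact_cutoff = 4.5
exclude_neighbors = 2
stability = 0.5

[interface]
chain_a = A
chain_b = B
interface_cutoff = 5.0
da_cutoff = 3.5
stride = 1
e_hbond = -1.5
e_elec = 1.0
elec_cutoff = 6.0
e_vdw = -0.2
vdw_lo = 3.0
vdw_hi = 5.0
hotspot_threshold = -2.0

[metrics]
rmsf_window = 0.5
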