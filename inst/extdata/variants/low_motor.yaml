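actin_conc: 20.0
motor_conc: 0.4
linker_conc: 2.0
diff_actin: 80.0
diff_linker: 8.0
diff_motor: 0.8
poly_plus: 0.151
poly_minus: 0.017
depoly_plus: 1.4
depoly_minus: 0.8
motor_bind: 0.2
motor_unbind0: 0.2
linker_bind: 0.009
linker_unbind0: 0.3
cylinder_length: 108.0
monomer_rise: 2.7
monomers_per_cylinder: 40
binding_sites_per_cylinder: 4
min_monomers: 3
bending_energy: 672.5
stretch_k: 100.0
excluded_volume_k: 100000.0
motor_head_k: 2.5
linker_k: 8.0
boundary_eps: 41.0
boundary_lambda: 2.7
anchor_k: 100.0
motor_unbind_force: 12.6
motor_stall_force: 15.0
linker_char_force: 17.2
poly_char_force: 1.5
motor_rest_min: 175.0
motor_rest_max: 225.0
linker_rest_min: 30.0
linker_rest_max: 40.0
box_x: 3000.0
box_y: 3000.0
box_z: 1250.0
compartment_size: 500.0
well_mixed: yes
probe_radius: 250.0
n_free: 300
n_attached: 30
seed_monomers: 40
heads_per_minifilament: 20
heads_per_side: 10
motor_walk_rate0: 0.2
chem_mech_interval: 0.5
motor_release_time: 5.0
snapshot_interval: 1.0
force_tol: 1.0
minimize_maxit: 100000.0
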