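feature,rho
R,0.338
G,0.540
B,0.076
H,0.417
S,0
V,0.381
L,0.557
a,-0.465
b,0.555
G_R,0.496
G_B,-0.076
B_R,0.076
S_H,-0.417
V_S,0.380
V_H,-0.352
L_a,0.464
L_b,0.496
b_a,-0.089
hist_mean,0.893
hist_sd,0.885
hist_skew,0.802
hist_smooth,0.884
T1_low_grad,-0.824
T2_high_grad,0.803
T3_gray_nonunif,-0.835
T4_grad_nonunif,-0.826
grad_mean,0.803
grad_sd,0.750
energy_mean,-0.312
entropy_mean,0.309
inertia_mean,0.204
corr_mean,0
energy_sd,0.147
entropy_sd,0.221
inertia_sd,0.190
corr_sd,0
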