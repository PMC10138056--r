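label,effect,se
alpha_trial,0.42,0.21
beta_trial,-0.08,0.14
gamma_trial,0.25,0.3
delta_trial,0.61,0.35
epsilon_trial,0.05,0.11
zeta_trial,-0.3,0.4
eta_trial,0.18,0.26
theta_trial,0.33,0.19
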