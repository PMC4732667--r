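feedback_nmda:
  tau_o: 5.0
  tau_c: 80.0
  g_peak: 0.11
  e_rev: 0.0
  delay: 1.0
  transmission_p: 1.0
  label: nmda
  mg:
    eta: 0.1
    gamma: 0.08
    mg_out: 0.5
feedback_ampa:
  tau_o: 0.1
  tau_c: 3.0
  g_peak: 0.11
  e_rev: 0.0
  delay: 1.0
  transmission_p: 1.0
  label: ampa
sensory_nmda:
  tau_o: 5.0
  tau_c: 80.0
  g_peak: 0.4
  e_rev: 0.0
  delay: 1.0
  transmission_p: 1.0
  label: nmda
  mg:
    eta: 0.1
    gamma: 0.08
    mg_out: 0.5
sensory_ampa:
  tau_o: 0.1
  tau_c: 3.0
  g_peak: 0.4
  e_rev: 0.0
  delay: 1.0
  transmission_p: 1.0
  label: ampa
gaba:
  tau_o: 1.5
  tau_c: 20.0
  g_peak: 2.0
  e_rev: -70.0
  delay: 1.0
  transmission_p: 1.0
  label: gaba
perfusion_nmda:
  tau_o: 5.0
  tau_c: 10000.0
  g_peak: 1.0
  e_rev: 0.0
  delay: 1.0
  transmission_p: 1.0
  label: nmda_perfusion
  mg:
    eta: 0.1
    gamma: 0.08
    mg_out: 0.5
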