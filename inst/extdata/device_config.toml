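# Device configuration template.
# Units are stated per key; both sections are optional -- missing keys
# fall back to the package defaults shown here.

[magstim]
capacitance = 150            # storage capacitance, microfarads
inductance = 16.35           # coil inductance, microhenries
coil_resistance = 0.08       # series loop resistance, ohms
initial_voltage = 2800       # capacitor charge voltage, volts (100% MSO)
freewheel_resistance = 0.1486364  # total freewheel-loop resistance, ohms (tau = L/R_fw = 110 us)

[ptms]
n_levels = 5                 # five-level (two-cell) topology
dc_link_voltage = 800        # per-cell DC-link voltage, volts (2V = 1600 V peak)
switching_frequency = 32     # kilohertz (13 x the ~2.46 kHz pulse fundamental)
pulse_duration = 1200        # nominal modulated span, microseconds
placement = "centered"       # pulse placement within each switching period
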