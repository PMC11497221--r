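# Standard Hansch sigma substituent constants (dimensionless).
# Editable: add or override entries; 'H: 0.0' must stay present and all
# values must lie in [-1, 1.5].
H: 0.0
p-OMe: -0.27
p-Me: -0.17
m-Me: -0.07
p-F: 0.06
m-OMe: 0.12
p-Cl: 0.23
p-Br: 0.23
m-Cl: 0.37
p-CF3: 0.54
m-NO2: 0.71
p-NO2: 0.78
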