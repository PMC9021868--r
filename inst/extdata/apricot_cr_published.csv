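cultivar,forcing_cp,correlation_cp,pls_cp,meiosis_cp,published_class
Berdejo,47.2,57.0,54.2,61.9,medium
Canino,40.2,57.0,54.8,53.2,low_medium
Corbato,47.5,55.7,54.9,59.7,medium
Goldrich,42.0,56.4,53.6,58.3,medium
Gonci Magyar,60.2,69.1,74.8,66.8,high
Harcot,45.0,54.8,53.3,59.8,medium
Henderson,69.1,69.1,53.6,70.9,high
Luizet,48.0,58.0,64.0,61.3,medium
Mitger,47.5,55.7,43.2,58.0,medium
Moniqui 1006,45.8,54.8,33.9,59.6,medium
Moniqui 2113,49.8,55.7,55.0,61.7,medium
Munoz,46.5,57.0,58.6,59.1,medium
Pandora,45.8,57.0,53.6,60.7,medium
Paviot,47.2,57.0,54.3,61.6,medium
Pepito del Rubio,41.2,55.7,53.3,58.9,medium
Stark Early Orange,60.4,70.7,76.7,71.4,high
Stella,69.9,81.7,72.9,84.8,high
Sun Glo,53.9,58.6,53.6,66.3,high
Tadeo,49.1,73.5,53.6,60.5,medium
Veecot,48.9,58.0,54.6,54.5,low_medium
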