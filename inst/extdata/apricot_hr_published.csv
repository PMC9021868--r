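cultivar,forcing_gdh,correlation_gdh,pls_gdh,meiosis_gdh,published_class
Berdejo,5278,4917,3905,4170,high
Canino,5026,4023,3634,4212,high
Corbato,4814,4520,3640,3900,low
Goldrich,4749,4086,4004,3712,low
Gonci Magyar,4288,4861,3448,4027,medium
Harcot,4767,4689,4209,3998,medium
Henderson,2866,4441,4604,4159,high
Luizet,5076,4732,4004,4120,high
Mitger,4777,4638,5326,4084,medium
Moniqui 1006,4921,4821,4811,4045,medium
Moniqui 2113,5144,4902,5305,4196,high
Munoz,5170,4650,3934,4185,high
Pandora,4924,4141,3723,3863,low
Paviot,5119,4781,3721,4135,high
Pepito del Rubio,5296,4638,3852,4019,medium
Stark Early Orange,4152,4123,3607,4053,medium
Stella,5936,4511,5468,3879,low
Sun Glo,4915,4953,5054,3789,low
Tadeo,4742,3000,4604,4126,high
Veecot,4564,4091,4660,4284,high
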