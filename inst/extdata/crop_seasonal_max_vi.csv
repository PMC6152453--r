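crop,year,ndvi_max,swdrvi_max
winter wheat,2011,0.79,0.63
winter rye,2011,0.88,0.75
spring barley,2011,0.85,0.71
potato,2011,0.77,0.61
winter wheat,2012,0.84,0.70
winter rye,2012,0.90,0.79
spring barley,2012,0.84,0.69
potato,2012,0.88,0.77
winter wheat,2013,0.88,0.76
winter rye,2013,0.85,0.72
spring barley,2013,0.89,0.78
potato,2013,0.70,0.56
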