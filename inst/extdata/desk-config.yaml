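# Desk-scale experiment configuration: all three environmental
# conditions, both network topologies, all five inference methods.
# Keys not listed here take the experimentConfig() defaults.
n: 100
E: 10
S: 100
grid: [0.0, 0.5, 1.0, 2.0, 2.5, 3.0, 3.5, 5.0, 10.0, 30.0, 50.0]
networks: [erdos_renyi, scale_free]
conditions: [normal, constant, spike]
methods: [bc3net, c3net, clr, mrnet, aracne]
masterSeed: 1
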