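arm,measure,amputation,cataract,mi,pvd,retinopathy,hf,ihd,renal_failure,stroke,neuropathy,ulcer,hypoglycemia,sum
dulaglutide,cost,93.30,286.90,465.01,138.49,46.74,930.87,702.91,5890.51,750.11,140.23,228.73,67.422,9741.24
dulaglutide,disutility,0.012,0.027,0.079,0.003,0.001,0.078,0.021,0.067,0.110,0.003,0.014,0.000,0.42
liraglutide,cost,96.96,289.22,467.37,139.20,50.39,1641.47,700.97,5919.25,724.05,125.95,245.51,67.296,10467.62
liraglutide,disutility,0.013,0.027,0.080,0.003,0.001,0.078,0.021,0.067,0.106,0.003,0.016,0.000,0.41
loxenatide,cost,84.71,278.21,445.44,150.14,43.25,907.02,715.82,6040.80,715.51,291.81,239.05,68.091,9979.85
loxenatide,disutility,0.011,0.026,0.076,0.004,0.001,0.076,0.022,0.068,0.105,0.003,0.015,0.000,0.41
semaglutide,cost,79.59,271.93,451.15,136.21,41.86,888.99,687.61,5598.65,698.56,136.03,198.93,67.049,9256.56
semaglutide,disutility,0.010,0.025,0.075,0.003,0.001,0.075,0.021,0.063,0.102,0.003,0.012,0.000,0.39
exenatide,cost,122.61,299.34,487.43,156.71,55.90,946.97,717.78,6608.31,746.22,145.34,252.77,67.671,10607.06
exenatide,disutility,0.016,0.028,0.083,0.004,0.001,0.079,0.022,0.075,0.110,0.003,0.016,0.000,0.44
lixisenatide,cost,135.67,300.39,480.52,150.71,57.10,950.71,685.60,6314.71,754.29,153.94,275.20,67.346,10326.18
lixisenatide,disutility,0.018,0.028,0.081,0.004,0.001,0.080,0.021,0.071,0.111,0.003,0.017,0.000,0.44
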