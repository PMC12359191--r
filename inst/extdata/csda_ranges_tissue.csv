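# CSDA ranges of charged particles in soft tissue / water, transcribed from
# the published radionuclide table (alpha ranges from NIST ASTAR in water,
# electron ranges from NIST ESTAR in ICRU 46 soft tissue). Printed values are
# rounded to two significant figures and are therefore not strictly monotone;
# build_range_table() applies isotonic regression before interpolation.
particle,energy_MeV,range_mm
alpha,5.70,0.046
alpha,5.71,0.046
alpha,5.73,0.047
alpha,5.76,0.047
alpha,5.79,0.046
alpha,5.83,0.048
alpha,5.87,0.048
alpha,5.98,0.049
alpha,6.04,0.050
alpha,6.06,0.050
alpha,6.13,0.051
alpha,6.34,0.054
alpha,6.62,0.058
alpha,6.82,0.061
alpha,7.07,0.064
alpha,7.39,0.070
alpha,7.45,0.071
alpha,8.38,0.085
alpha,8.78,0.091
alpha,8.79,0.091
electron,0.00026,0.00002
electron,0.00035,0.00002
electron,0.00040,0.00002
electron,0.00045,0.00002
electron,0.010,0.0025
electron,0.0203,0.0088
electron,0.0306,0.0182
electron,0.127,0.215
electron,0.134,0.23
electron,0.154,0.215
electron,0.182,0.39
electron,0.188,0.41
electron,0.219,0.52
electron,0.225,0.54
electron,0.323,0.94
electron,0.583,2.2
electron,0.672,2.0
electron,0.765,3.1
electron,0.934,4.0
electron,1.490,7.1
electron,1.854,9.0
electron,2.120,10.0
electron,2.280,11.0
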