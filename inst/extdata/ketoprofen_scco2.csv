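temperature_K,pressure_bar,solubility
308.15,160,2.21e-05
308.15,200,2.56e-05
308.15,240,2.87e-05
308.15,280,3.21e-05
308.15,320,3.45e-05
308.15,360,4.23e-05
308.15,400,4.56e-05
318.15,160,5.01e-05
318.15,200,6.58e-05
318.15,240,7.68e-05
318.15,280,9.01e-05
318.15,320,1.12e-04
318.15,360,1.03e-04
318.15,400,1.20e-04
328.15,160,7.01e-05
328.15,200,1.16e-04
328.15,240,1.75e-04
328.15,280,2.20e-04
328.15,320,2.54e-04
328.15,360,3.24e-04
328.15,400,3.59e-04
338.15,160,1.01e-04
338.15,200,2.45e-04
338.15,240,3.25e-04
338.15,280,4.92e-04
338.15,320,5.79e-04
338.15,360,6.87e-04
338.15,400,7.12e-04
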