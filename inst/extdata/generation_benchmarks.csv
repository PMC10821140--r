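dataset,model,validity,uniqueness,novelty,success_rate
moses,CharRNN,0.975,0.999,0.842,0.820
moses,VAE,0.977,0.998,0.695,0.678
moses,AAE,0.937,0.997,0.793,0.741
moses,LatentGAN,0.897,0.997,0.949,0.849
moses,JT-VAE,1.0,0.999,0.914,0.913
moses,MolGPT,0.995,1.0,0.781,0.777
moses,ConGPT-unfrozen,0.992,1.0,0.791,0.785
moses,ConGPT-frozen,0.991,1.0,0.834,0.826
guacamol,SMILES-LSTM,0.959,1.0,0.912,0.875
guacamol,VAE,0.870,0.999,0.974,0.847
guacamol,AAE,0.822,1.0,0.998,0.820
guacamol,MolGPT,0.979,0.998,0.958,0.936
guacamol,ConGPT-unfrozen,0.968,0.999,0.968,0.936
guacamol,ConGPT-frozen,0.961,0.999,0.975,0.936
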