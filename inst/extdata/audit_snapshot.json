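{"total_params":5816962,"total_flops":14685548800,"params_m":5.816962,"gflops":14.6855488}
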