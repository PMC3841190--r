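[{"size":6,"threshold":0.008},{"size":7,"threshold":0.287},{"size":8,"threshold":0.473},{"size":9,"threshold":0.689},{"size":10,"threshold":0.841},{"size":11,"threshold":0.847},{"size":12,"threshold":0.884},{"size":13,"threshold":0.884},{"size":14,"threshold":0.884},{"size":15,"threshold":0.884},{"size":16,"threshold":0.884},{"size":17,"threshold":0.884},{"size":18,"threshold":0.884},{"size":19,"threshold":0.884},{"size":20,"threshold":0.884},{"size":21,"threshold":0.884},{"size":22,"threshold":0.884},{"size":23,"threshold":0.884},{"size":24,"threshold":0.884},{"size":25,"threshold":0.884},{"size":26,"threshold":0.884},{"size":27,"threshold":0.884}]
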