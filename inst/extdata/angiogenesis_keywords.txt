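angiogenesis
angiogenic
neovascularization
neovascular
vasculogenesis
tumor vasculature
tumour vasculature
vascular endothelial growth
blood vessel formation
endothelial sprouting
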