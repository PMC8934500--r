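>wt_synthetic_cc_domain synthetic stand-in coiled-coil sequence (not natural SIP)
LEAIEAKLQAVENKLASIEQKLEAIKAELTAVSEKLQAIENRLAAI
>K21W_synthetic_cc_domain
LEAIEAKLQAVENKLASIEQWLEAIKAELTAVSEKLQAIENRLAAI
>T30R_S33E_synthetic_cc_domain
LEAIEAKLQAVENKLASIEQKLEAIKAELRAVEEKLQAIENRLAAI
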