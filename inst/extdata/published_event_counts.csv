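indicator,observed_m11,observed_ssg
pass_forward,2167,2526
tackle,619,758
take_on,601,775
applying_pressure,439,524
pass_interception,418,414
defensive_aerial_duel,303,40
staying_in_front,195,389
offensive_aerial_duel,195,47
dribble,165,247
shot_on_target,68,222
chance_created,43,118
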