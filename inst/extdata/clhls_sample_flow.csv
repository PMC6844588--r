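component,count
interviewed_2002,11784
enrolled_2005,5095
enrolled_2008,5883
enrolled_2011,917
excluded_no_followup,3981
excluded_incomplete_baseline,79
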