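study,total_billions_2017,scope
tyler,10.1,"meta-analysis central estimates, four device/procedure infections, 2011 central burden"
zimlichman,7.2,"meta-analysis central estimates, four device/procedure infections, 2011 central burden"
analogy,8.7,"this framework, same four infections and burden"
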