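token	emotion
happy	joy
happy	trust
furious	anger
scared	fear
shocked	surprise
gloomy	sadness
eager	anticipation
disgusted	disgust
reliable	trust
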