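{"type":"Feature","properties":{"synthetic":true},"geometry":{"type":"Polygon","coordinates":[[[1000,250],[1450,180],[1850,320],[1950,650],[1700,900],[1250,950],[980,750],[900,450],[1000,250]]]}}
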