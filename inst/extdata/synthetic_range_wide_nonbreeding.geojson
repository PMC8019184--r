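{"type":"Feature","properties":{"synthetic":true},"geometry":{"type":"Polygon","coordinates":[[[300,100],[1100,0],[2100,80],[2900,200],[3300,500],[3200,1000],[2500,1250],[1500,1300],[700,1150],[200,700],[300,100]]]}}
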