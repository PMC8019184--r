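{"type":"Feature","properties":{"synthetic":true},"geometry":{"type":"Polygon","coordinates":[[[900,2650],[1350,2600],[1700,2750],[1800,3100],[1650,3400],[1250,3500],[950,3350],[820,3000],[900,2650]]]}}
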