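marker,domain,axis,count
ACR,trajectory,x,52
ACR,trajectory,y,0
ACR,trajectory,z,0
ACR,acceleration,x,26
ACR,acceleration,y,14
ACR,acceleration,z,35
ACR,acceleration,module,38
ACR,velocity,x,29
ACR,velocity,y,9
ACR,velocity,z,30
ACR,velocity,module,35
ACR,displacement,x,42
ACR,displacement,y,11
ACR,displacement,z,4
ACR,displacement,module,13
MPH,trajectory,x,47
MPH,trajectory,y,6
MPH,trajectory,z,14
MPH,acceleration,x,34
MPH,acceleration,y,12
MPH,acceleration,z,35
MPH,acceleration,module,62
MPH,velocity,x,42
MPH,velocity,y,7
MPH,velocity,z,53
MPH,velocity,module,62
MPH,displacement,x,37
MPH,displacement,y,30
MPH,displacement,z,3
MPH,displacement,module,15
LEP,trajectory,x,31
LEP,trajectory,y,3
LEP,trajectory,z,11
LEP,acceleration,x,2
LEP,acceleration,y,3
LEP,acceleration,z,4
LEP,acceleration,module,18
LEP,velocity,x,3
LEP,velocity,y,0
LEP,velocity,z,0
LEP,velocity,module,7
LEP,displacement,x,14
LEP,displacement,y,3
LEP,displacement,z,2
LEP,displacement,module,3
FN,trajectory,x,1
FN,trajectory,y,8
FN,trajectory,z,11
FN,acceleration,x,5
FN,acceleration,y,11
FN,acceleration,z,29
FN,acceleration,module,7
FN,velocity,x,3
FN,velocity,y,0
FN,velocity,z,7
FN,velocity,module,0
FN,displacement,x,0
FN,displacement,y,6
FN,displacement,z,3
FN,displacement,module,12
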