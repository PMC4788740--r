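id,timestamp,text,author
m01,2015-01-02T10:00:00Z,loving my new vape pen so much,casualuser1
m02,2015-01-03T11:30:00Z,best smoked brisket in town,bbqfan
m03,2015-01-05T09:15:00Z,switched to an e-cig last week,quitter22
m04,2015-01-08T14:00:00Z,this atomizer perfume bottle is elegant,glamshop
m05,2015-01-10T16:45:00Z,my atomizer coil burned out again,cloudchaser
m06,2015-01-12T08:20:00Z,monday traffic is unreal,commuter9
m07,2015-01-15T19:05:00Z,check out @blucigs for deals,promofan
m08,2015-01-18T12:10:00Z,she is smoking hot in that dress,randomguy
m09,2015-01-21T17:30:00Z,vaping after lunch with friends,cloudchaser
m10,2015-01-25T20:00:00Z,new #vapelife post is up,influenzer
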